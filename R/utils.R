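# internal helpers shared across modules

# run code with a temporarily seeded RNG, restoring global state afterwards
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# accept GrayImage or plain matrix; return a plain numeric matrix
asImageMatrix <- function(image, arg = "image") {
  if (is(image, "GrayImage")) image <- image@.Data
  if (!is.numeric(image) || length(dim(image)) != 2L)
    stop(sprintf("'%s' must be a 2-D numeric matrix (or GrayImage)", arg))
  storage.mode(image) <- "double"
  unclass(image)
}

stopIfNegative <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(sprintf("'%s' must be nonnegative", name))
  invisible(x)
}
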