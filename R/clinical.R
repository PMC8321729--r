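# Two-group inference from summary statistics: Welch (or pooled) t test
# from mean/sd/n, and the Fisher exact test on 2x2 counts. These are the
# only tests the bundled clinical summaries support — no individual-level
# data exist.

#' Construct a group summary
#'
#' @param mean group mean, in the source's units.
#' @param sd group standard deviation (> 0).
#' @param n group size (>= 2).
#' @return a [GroupSummary-class].
#' @export
groupSummary <- function(mean, sd, n) {
  new("GroupSummary", mean = as.numeric(mean), sd = as.numeric(sd),
      n = as.integer(n))
}

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary: %.4g +/- %.4g (n = %d)\n",
              object@mean, object@sd, object@n))
})

#' Two-sample t test from summary statistics
#'
#' Computes the two-sided two-sample t test from group means, standard
#' deviations and sizes alone. The default is Welch's form,
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' degrees of freedom, which does not assume equal variances; the pooled
#' (Student) form is available via \code{pooled = TRUE}. For two groups the
#' pooled test is p-equivalent to a one-way analysis of variance.
#'
#' @param g1,g2 [GroupSummary-class] objects (see [groupSummary()]).
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return an object of class \code{"htest"}.
#' @examples
#' welchTFromSummary(groupSummary(313.23, 19.67, 28),
#'                   groupSummary(377.67, 21.56, 28))
#' @export
welchTFromSummary <- function(g1, g2, pooled = FALSE) {
  stopifnot(is(g1, "GroupSummary"), is(g2, "GroupSummary"))
  validObject(g1); validObject(g2)
  m1 <- g1@mean; s1 <- g1@sd; n1 <- g1@n
  m2 <- g2@mean; s2 <- g2@sd; n2 <- g2@n
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample pooled t test from summary statistics"
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch two-sample t test from summary statistics"
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(
    statistic = c(t = tstat),
    parameter = c(df = df),
    p.value = p,
    estimate = c(`mean difference` = m1 - m2),
    method = method,
    alternative = "two.sided",
    data.name = sprintf("%.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)",
                        m1, s1, n1, m2, s2, n2)
  ), class = "htest")
}

#' Fisher exact test on a 2x2 table
#'
#' Exact two-sided test of association for a 2x2 contingency table, with
#' the conventional two-sided rule: the p-value is the sum of the
#' hypergeometric point probabilities not exceeding that of the observed
#' table (a relative tolerance of 1e-7 guards ties against rounding).
#'
#' @param tab 2x2 matrix of nonnegative integer counts; rows are groups,
#'   columns event/no-event.
#' @return an object of class \code{"htest"}.
#' @examples
#' fisherExact2x2(matrix(c(2, 9, 26, 19), 2))  # p ~= 0.0403
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)) || anyNA(tab) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("'tab' must be a 2x2 matrix of nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column margin of 'tab' must be positive")
  k1 <- sum(tab[, 1])      # total events
  n1 <- sum(tab[1, ])      # group-1 size
  N <- sum(tab)
  support <- max(0, n1 + k1 - N):min(n1, k1)
  pk <- stats::dhyper(support, k1, N - k1, n1)
  pobs <- stats::dhyper(tab[1, 1], k1, N - k1, n1)
  p <- min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
  structure(list(
    statistic = c(`observed a` = tab[1, 1]),
    parameter = NULL,
    p.value = p,
    method = "Fisher exact test for a 2x2 table (two-sided)",
    alternative = "two.sided",
    data.name = paste(tab, collapse = ", ")
  ), class = "htest")
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, offered as the
#' large-sample alternative to [fisherExact2x2()].
#'
#' @inheritParams fisherExact2x2
#' @return an object of class \code{"htest"}.
#' @export
chisq2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("'tab' must be a 2x2 matrix")
  stats::chisq.test(tab, correct = FALSE)
}
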