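# Independent oracles, built differently from the package internals.

# Single-level orthonormal Haar analysis matrix for even n, constructed as
# an explicit block orthogonal matrix: first n/2 rows average adjacent
# pairs, last n/2 rows difference them, both scaled by 1/sqrt(2).
haarMatrixOracle <- function(n) {
  stopifnot(n %% 2 == 0)
  H <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    H[k, 2 * k - 1] <- 1 / sqrt(2)
    H[k, 2 * k] <- 1 / sqrt(2)
    H[n / 2 + k, 2 * k - 1] <- 1 / sqrt(2)
    H[n / 2 + k, 2 * k] <- -1 / sqrt(2)
  }
  H
}

# Two-sided Fisher exact p by direct enumeration with binomial-coefficient
# ratios (the implementation uses dhyper); the 1e-7 relative fuzz at ties
# is part of the conventional two-sided rule.
fisherOracle <- function(a, b, c, d) {
  k1 <- a + c
  n1 <- a + b
  N <- a + b + c + d
  ks <- max(0, n1 + k1 - N):min(n1, k1)
  pk <- choose(k1, ks) * choose(N - k1, n1 - ks) / choose(N, n1)
  pobs <- choose(k1, a) * choose(N - k1, n1 - a) / choose(N, n1)
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

# rescale a sample so its mean and sd match a target exactly; lets
# stats::t.test on full data stand as an oracle for the summary-based test
matchSummary <- function(x, mean, sd) {
  mean + (x - mean(x)) * sd / sd(x)
}

randomImage <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

sumAbsGradient <- function(x) {
  sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
}
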