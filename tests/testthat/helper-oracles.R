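# Independent oracles used to cross-check the package implementation.

TISSUE_CLASSES <- stromanmr:::TISSUE_CLASSES

# One-component PLS1 by the textbook NIPALS recursion (no orthogonal
# filtering). Kept deliberately separate from the package's OPLS code.
nipals_pls1 <- function(X, y) {
  w <- t(X) %*% y
  w <- w / sqrt(sum(w^2))
  t1 <- X %*% w
  p <- t(X) %*% t1 / sum(t1^2)
  q <- sum(y * t1) / sum(t1^2)
  list(w = w, t = t1, p = p, q = q)
}

# brute-force trapezoid quadrature on a dense grid
trapz_oracle <- function(f, lo, hi, n = 200001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# two well-separated Gaussian clouds for discriminant tests
two_clouds <- function(n_per = 30, K = 10, delta = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * K), n_per),
             matrix(rnorm(n_per * K, mean = 0), n_per))
  X[seq_len(n_per), 1] <- X[seq_len(n_per), 1] + delta
  labels <- rep(c("pos", "neg"), each = n_per)
  list(X = scale(X), labels = labels)
}

location_median_targets <- function() {
  rbind(
    T       = c(cancer = 30, intratumoral_fibrosis = 70,
                extratumoral_connective = 0, fat = 0, glandular = 0,
                immune = 0, necrosis = 0),
    TB      = c(3, 30, 5, 20, 0, 5, 0),
    N_lt1cm = c(0, 0, 7.5, 30, 0, 0, 0),
    N_eq1cm = c(0, 0, 22.5, 75, 0, 0, 0),
    N_gt1cm = c(0, 0, 0, 100, 0, 0, 0)
  )
}
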