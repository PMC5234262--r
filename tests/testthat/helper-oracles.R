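# Independent oracles, deliberately written without reusing package internals.

# Exhaustive Otsu scan: try every threshold, recompute class statistics from
# the definition each time.
brute_force_otsu <- function(p) {
  L <- length(p)
  lev <- 0:(L - 1)
  mu_T <- sum(p * lev)
  Jvec <- rep(-Inf, L - 1)
  for (t in 1:(L - 1)) {
    w0 <- sum(p[1:t])
    w1 <- sum(p[(t + 1):L])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lev[1:t] * p[1:t]) / w0
    mu1 <- sum(lev[(t + 1):L] * p[(t + 1):L]) / w1
    Jvec[t] <- w0 * (mu0 - mu_T)^2 + w1 * (mu1 - mu_T)^2
  }
  best_J <- max(Jvec)
  # thresholds whose objective is indistinguishable from the maximum at the
  # comparison tolerance count as ties (smallest wins in the implementation)
  ties <- which(Jvec >= best_J - 1e-9 * max(1, abs(best_J)))
  list(t = ties[1], ties = ties, J = best_J, Jvec = Jvec)
}

expect_otsu_matches_oracle <- function(got, oracle) {
  expect_true(got$t %in% oracle$ties)
  if (length(oracle$ties) == 1L) expect_equal(got$t, oracle$t)
  expect_equal(got$J, oracle$J, tolerance = 1e-9)
}

# Scalar evaluation of the toroidal maps and operators, step by step.
scalar_toroidal <- function(amp, u, v, r, R) {
  f <- 1 / amp^r
  thd <- (R + cos(2 * pi * f * u)) * cos(2 * pi * atan(f))
  tvd <- (R + cos(2 * pi * f * v)) * sin(2 * pi * atan(f))
  list(f = f, thd = thd, tvd = tvd,
       t_a = amp * (tvd + thd), t_p = amp^2 * (tvd * thd))
}

# Morphological erosion by the 4-neighbour cross, by explicit shifting.
erode4 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  pad <- matrix(FALSE, n + 2L, k + 2L)
  pad[2:(n + 1), 2:(k + 1)] <- m != 0
  out <- pad[2:(n + 1), 2:(k + 1)] &
    pad[1:n, 2:(k + 1)] & pad[3:(n + 2), 2:(k + 1)] &
    pad[2:(n + 1), 1:k] & pad[2:(n + 1), 3:(k + 2)]
  out
}

random_histogram <- function(bins = 256L) {
  k <- sample(2:8, 1)
  centers <- sample(0:(bins - 1), k)
  w <- runif(k); w <- w / sum(w)
  p <- numeric(bins)
  for (i in seq_len(k)) {
    sd_ <- runif(1, 1, 20)
    d <- stats::dnorm(0:(bins - 1), centers[i], sd_)
    p <- p + w[i] * d / sum(d)
  }
  p / sum(p)
}

tiny_rgb <- function(n = 4, m = 5, seed = 1) {
  with_seed_test(seed, array(runif(n * m * 3, 0, 255), c(n, m, 3)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
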