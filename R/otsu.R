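#' Histogram of normalized values on [0, 1]
#'
#' Equal-width bins over `[0, 1]` with the last bin closed on the right, as in
#' 8-bit gray-level histograms; a value `x` falls into bin
#' `min(floor(x * bins), bins - 1)` (0-based).
#'
#' @param values Numeric matrix or vector with entries in `[0, 1]`.
#' @param bins Number of bins (default 256, the 8-bit gray-level convention).
#' @return Object of class `"torusseg_histogram"`: list with `probs`
#'   (probabilities summing to 1), `counts`, and `bins`.
#' @export
gray_histogram <- function(values, bins = 256L) {
  v <- as.numeric(values)
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    stopf("histogram values must lie in [0, 1]", class = "torusseg_invalid_input")
  if (!is.finite(bins) || bins < 2)
    stopf("`bins` must be >= 2", class = "torusseg_invalid_parameter")
  bins <- as.integer(bins)
  idx <- pmin(floor(v * bins), bins - 1L)       # right-closed last bin
  counts <- tabulate(idx + 1L, nbins = bins)
  structure(list(probs = counts / length(v), counts = counts, bins = bins),
            class = "torusseg_histogram")
}

#' Otsu threshold by between-class variance maximization
#'
#' Splits the gray levels `0 .. L-1` at a threshold `t` into class `C0`
#' (levels `< t`) and `C1` (levels `>= t`) and picks the `t` maximizing the
#' between-class objective
#' `J(t) = w0 (mu0 - muT)^2 + w1 (mu1 - muT)^2`,
#' where `w0, w1` are the class probabilities, `mu0, mu1` the class mean
#' levels and `muT` the global mean. Only thresholds with mass in both classes
#' are candidates; ties are broken at the smallest maximizing `t` so the
#' result is deterministic. The returned result satisfies the mixture
#' identities `w0 + w1 = 1` and `w0 mu0 + w1 mu1 = muT`.
#'
#' @param hist A `"torusseg_histogram"` (or a bare probability vector).
#' @return Object of class `"torusseg_otsu"`: list with `t` (bin index in
#'   `1 .. L-1`), `t_value` (`t / L`, the threshold on the `[0, 1]` value
#'   scale), `J`, `class_means` (mu0, mu1), `class_weights` (w0, w1) and
#'   `global_mean` (all means on the bin-index scale).
#'   A histogram with fewer than two nonempty bins (a constant image) raises a
#'   `"torusseg_degenerate_histogram"` error.
#' @export
otsu_threshold <- function(hist) {
  p <- if (inherits(hist, "torusseg_histogram")) hist$probs else as.numeric(hist)
  L <- length(p)
  if (L < 2L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stopf("`hist` must be a probability vector over >= 2 bins",
          class = "torusseg_invalid_input")
  if (sum(p > 0) < 2L)
    stopf("degenerate histogram: fewer than two nonempty bins",
          class = "torusseg_degenerate_histogram")
  lev <- 0:(L - 1)
  mu_T <- sum(p * lev)
  cw <- cumsum(p)
  cm <- cumsum(p * lev)
  t_cand <- 1:(L - 1)
  w0 <- cw[t_cand]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- cm[t_cand] / w0
  mu1 <- (mu_T - cm[t_cand]) / w1
  J <- w0 * (mu0 - mu_T)^2 + w1 * (mu1 - mu_T)^2
  J[!valid] <- -Inf
  t <- which.max(J)                              # which.max takes the first tie
  structure(list(t = t, t_value = t / L, J = J[t],
                 class_means = c(mu0 = mu0[t], mu1 = mu1[t]),
                 class_weights = c(w0 = w0[t], w1 = w1[t]),
                 global_mean = mu_T),
            class = "torusseg_otsu")
}

#' @export
print.torusseg_otsu <- function(x, ...) {
  cat(sprintf("<torusseg_otsu> t = %d (value %.4f), J = %.4f, w = (%.3f, %.3f)\n",
              x$t, x$t_value, x$J, x$class_weights[1], x$class_weights[2]))
  invisible(x)
}

#' Binarize a decomposition level into the Omega1/Omega2 partition
#'
#' The threshold is optimized on the histogram of the normalized product
#' operator `T_p` and then applied, on the `[0, 1]` value scale, to the field
#' selected by `target` (default the additive operator `T_a`, the printed
#' reading of the method; `target = "tp"` applies it to `T_p` itself).
#' `Omega1` collects pixels with value `<= t_value` (the low, dark class --
#' wound tissue has low amplitude), `Omega2` the rest: the two masks always
#' partition the pixel set.
#'
#' @param level A `"torusseg_level"` from [toroidal_operators()].
#' @param bins Histogram bin count (default 256).
#' @param target Field the threshold is applied to: `"ta"` or `"tp"`.
#' @return Object of class `"torusseg_binarization"`: list with binary
#'   matrices `omega1`, `omega2`, the `"torusseg_otsu"` `threshold`, and `r`.
#' @export
binarize_level <- function(level, bins = 256L, target = c("ta", "tp")) {
  if (!inherits(level, "torusseg_level"))
    stopf("`level` must be a torusseg_level", class = "torusseg_invalid_input")
  target <- match.arg(target)
  thr <- otsu_threshold(gray_histogram(level$t_p_norm, bins))
  field <- if (target == "ta") level$t_a_norm else level$t_p_norm
  omega1 <- as_mask(field <= thr$t_value)
  structure(list(omega1 = omega1, omega2 = as_mask(1L - omega1),
                 threshold = thr, r = level$r),
            class = "torusseg_binarization")
}
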