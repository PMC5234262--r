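#' Digital image correlation between two images
#'
#' Pearson product-moment correlation computed over all pixels,
#' `rho = sum((A - mean(A)) (B - mean(B))) / sqrt(sum((A - mean(A))^2) * sum((B - mean(B))^2))`,
#' the accuracy measure used to compare a computed mask with its ground truth.
#' Binary masks and grayscale images are both accepted; when resolutions
#' differ the second image is resampled to the first with nearest-neighbour
#' interpolation (ground truth against a mask computed at processing
#' resolution).
#'
#' @param a,b Equal-shape numeric matrices (masks or grayscale images),
#'   neither constant.
#' @return Correlation in `[-1, 1]` (scalar).
#' @examples
#' image_correlation(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
#' # 1/sqrt(3)
#' @export
image_correlation <- function(a, b) {
  a <- matrix(as.numeric(a), nrow(a), ncol(a))
  b <- matrix(as.numeric(b), nrow(b), ncol(b))
  if (!identical(dim(a), dim(b))) {
    idx_r <- pmax(1L, round(seq_len(nrow(a)) * nrow(b) / nrow(a)))
    idx_c <- pmax(1L, round(seq_len(ncol(a)) * ncol(b) / ncol(a)))
    b <- b[idx_r, idx_c, drop = FALSE]
  }
  da <- a - mean(a)
  db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0)
    stopf("correlation undefined: %s image is constant",
          if (va == 0) "first" else "second",
          class = "torusseg_undefined_correlation")
  sum(da * db) / sqrt(va * vb)
}

#' Batch evaluation of segmentation results against ground truth
#'
#' Scores each mask/truth pair with [image_correlation()] and summarizes the
#' per-image correlations. Pairs whose correlation is undefined (a constant
#' mask, e.g. an empty segmentation) are recorded as failures and excluded
#' from the moments.
#'
#' @param masks List of binary masks or `"torusseg_segmentation"` objects.
#' @param truths List of ground-truth binary masks, same length.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Object of class `"torusseg_eval"`: list with `per_image` (tibble of
#'   id, rho, failed) and `summary` (tibble of n, n_failed, mean, sd, min,
#'   max over the defined correlations).
#' @export
evaluate_batch <- function(masks, truths, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.list(masks) || !is.list(truths) || !length(masks) ||
      length(masks) != length(truths))
    stopf("`masks` and `truths` must be nonempty lists of equal length",
          class = "torusseg_invalid_input")
  rho <- vapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    if (inherits(m, "torusseg_segmentation")) m <- m$mask
    tryCatch(image_correlation(m, truths[[i]]),
             torusseg_undefined_correlation = function(e) NA_real_)
  }, 0)
  ok <- !is.na(rho)
  vals <- rho[ok]
  sdv <- if (length(vals) < 2) ifelse(length(vals) == 1, 0, NA_real_)
         else if (sd_type == "sample") sd(vals)
         else sqrt(mean((vals - mean(vals))^2))
  structure(list(
    per_image = tibble::tibble(id = seq_along(rho), rho = rho, failed = !ok),
    summary = tibble::tibble(n = length(rho), n_failed = sum(!ok),
                             mean = mean(vals), sd = sdv,
                             min = suppressWarnings(min(vals)),
                             max = suppressWarnings(max(vals)),
                             sd_type = sd_type)),
    class = "torusseg_eval")
}

#' @export
print.torusseg_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<torusseg_eval> n = %d (%d failed)\n", s$n, s$n_failed))
  cat(sprintf("  rho: mean %.3f, sd %.3f (%s), min %.3f, max %.3f\n",
              s$mean, s$sd, s$sd_type, s$min, s$max))
  invisible(x)
}
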