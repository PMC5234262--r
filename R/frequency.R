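#' Per-pixel synthetic frequency field
#'
#' Computes `f(m, n; r) = 1 / A~(m, n)^r`, the synthetic frequency assigned to
#' each pixel from its grayscale amplitude. `A~ = A + amplitude_offset` maps
#' stored 8-bit amplitudes `[0, 255]` onto the working range `[1, 256]`, which
#' removes the singularity at zero amplitude. Frequency is inversely related to
#' amplitude: dark pixels get high frequencies, bright pixels low ones, and the
#' exponent `r` controls how sharply the field varies.
#'
#' @param gray Amplitude matrix in `[0, 255]`.
#' @param r Frequency parameter, a positive real.
#' @param amplitude_offset Shift added to stored amplitudes (default 1).
#' @return Matrix of frequencies in `(0, 1]` (given `amplitude_offset >= 1`),
#'   with the generating `r` attached as attribute `"r"`.
#' @examples
#' synthetic_frequency(matrix(0), r = 2)    # amplitude 0 -> A~ = 1 -> f = 1
#' synthetic_frequency(matrix(3), r = 0.5)  # A~ = 4 -> f = 0.5
#' @export
synthetic_frequency <- function(gray, r, amplitude_offset = 1) {
  check_gray(gray)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stopf("frequency parameter `r` must be a positive real (got %s)",
          format(r)[1], class = "torusseg_invalid_parameter")
  f <- 1 / (gray + amplitude_offset)^r
  attr(f, "r") <- r
  f
}

#' Evenly spaced frequency-parameter grid
#'
#' @param r_min,r_max Grid bounds, `0 < r_min <= r_max`.
#' @param levels Number of grid points; `levels = 1` uses `r_min`.
#' @return Numeric vector of `levels` values spanning `[r_min, r_max]`.
#' @export
r_grid <- function(r_min = 0.013, r_max = 0.015, levels = 30L) {
  if (!is.finite(r_min) || !is.finite(r_max) || r_min <= 0 || r_min > r_max)
    stopf("need 0 < r_min <= r_max (got %s, %s)", format(r_min), format(r_max),
          class = "torusseg_invalid_parameter")
  if (!is.finite(levels) || levels < 1)
    stopf("`levels` must be >= 1", class = "torusseg_invalid_parameter")
  if (levels == 1) return(r_min)
  seq(r_min, r_max, length.out = levels)
}

#' Sweep of synthetic-frequency fields over a frequency-parameter grid
#'
#' One contrast level is generated per grid point; the default grid (30 levels
#' over `[0.013, 0.015]`) is the sweep used for wound segmentation.
#'
#' @inheritParams synthetic_frequency
#' @inheritParams r_grid
#' @return List of frequency matrices, one per `r`, each carrying its `"r"`
#'   attribute.
#' @export
frequency_sweep <- function(gray, r_min = 0.013, r_max = 0.015, levels = 30L,
                            amplitude_offset = 1) {
  rs <- r_grid(r_min, r_max, levels)
  lapply(rs, function(r) synthetic_frequency(gray, r, amplitude_offset))
}
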