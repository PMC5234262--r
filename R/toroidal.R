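#' Coordinate grids for the toroidal decomposition
#'
#' Builds the horizontal (`u`) and vertical (`v`) coordinate maps the torus
#' parametrization is evaluated on. Each row of `u` is the symmetric ramp of
#' `width` evenly spaced values spanning `[-(width-1)/width, (width-1)/width]`;
#' each column of `v` is the analogous ramp over `height`. The ramps are
#' symmetric about 0 and contained in `[-1, 1]`.
#'
#' @param height,width Image dimensions in pixels (rows, columns).
#' @return List with matrices `u` and `v`, both `height x width`.
#' @export
make_grids <- function(height, width) {
  if (!is.finite(height) || !is.finite(width) || height < 1 || width < 1)
    stopf("image dimensions must be positive (got %s x %s)",
          format(height), format(width), class = "torusseg_invalid_parameter")
  height <- as.integer(height); width <- as.integer(width)
  ramp <- function(k) if (k == 1L) 0 else seq(-(k - 1) / k, (k - 1) / k, length.out = k)
  list(u = matrix(ramp(width), height, width, byrow = TRUE),
       v = matrix(ramp(height), height, width))
}

check_shapes <- function(...) {
  ds <- lapply(list(...), dim)
  if (length(unique(lapply(ds, paste, collapse = "x"))) != 1L)
    stopf("shape mismatch between inputs (%s)",
          paste(vapply(ds, paste, "", collapse = "x"), collapse = " vs "),
          class = "torusseg_invalid_input")
  invisible(TRUE)
}

#' Toroidal horizontal decomposition
#'
#' Evaluates, per pixel, `[R + cos(2 pi f u)] * cos(2 pi arctan(f))` using each
#' pixel's own synthetic frequency `f` and horizontal coordinate `u`. This is
#' the x-map of the torus surface with the angular parameters re-expressed in
#' terms of the frequency field.
#'
#' @param grids Coordinate grids from [make_grids()].
#' @param freq Synthetic-frequency matrix (see [synthetic_frequency()]).
#' @param R Major torus radius in pixels (default 100).
#' @return Numeric matrix of the same shape.
#' @export
thd <- function(grids, freq, R = 100) {
  check_shapes(grids$u, freq)
  out <- (R + cos(2 * pi * freq * grids$u)) * cos(2 * pi * atan(freq))
  matrix(as.numeric(out), nrow(out), ncol(out))
}

#' Toroidal vertical decomposition
#'
#' The y-map counterpart of [thd()]:
#' `[R + cos(2 pi f v)] * sin(2 pi arctan(f))` per pixel.
#'
#' @inheritParams thd
#' @return Numeric matrix of the same shape.
#' @export
tvd <- function(grids, freq, R = 100) {
  check_shapes(grids$v, freq)
  out <- (R + cos(2 * pi * freq * grids$v)) * sin(2 * pi * atan(freq))
  matrix(as.numeric(out), nrow(out), ncol(out))
}

#' Additive and product toroidal operators for one contrast level
#'
#' Combines the shifted amplitude `A~ = A + amplitude_offset` with the two
#' decompositions through elementwise (Hadamard) products:
#' `T_a = A~ o (TVD + THD)` and `T_p = A~^2 o (TVD o THD)`. Both operators are
#' stored normalized, `T_bar = |T| / max(|T|)`, so each level lives on `[0, 1]`
#' with maximum exactly 1. All operations are strictly per pixel: no
#' neighbourhood enters, so the transform commutes with any permutation of
#' pixel positions applied jointly to amplitude and coordinates.
#'
#' @param gray Amplitude matrix in `[0, 255]`.
#' @param grids Coordinate grids from [make_grids()].
#' @param freq Frequency matrix for this level (carries its `r`).
#' @param R Major torus radius in pixels.
#' @param amplitude_offset Shift applied to stored amplitudes (default 1, the
#'   same convention as [synthetic_frequency()]).
#' @return Object of class `"torusseg_level"`: list with `thd`, `tvd`,
#'   `t_a_norm`, `t_p_norm` matrices and the generating `r`.
#'   A level whose additive or product operator is identically zero cannot be
#'   normalized and raises a `"torusseg_degenerate_level"` error (the sweep
#'   skips and logs such levels).
#' @export
toroidal_operators <- function(gray, grids, freq, R = 100, amplitude_offset = 1) {
  check_gray(gray)
  check_shapes(gray, grids$u, grids$v, freq)
  amp <- gray + amplitude_offset
  h <- thd(grids, freq, R)
  v <- tvd(grids, freq, R)
  t_a <- amp * (v + h)
  t_p <- amp^2 * (v * h)
  ma <- max(abs(t_a)); mp <- max(abs(t_p))
  if (ma == 0 || mp == 0)
    stopf("degenerate level (r = %s): %s operator is identically zero",
          format(attr(freq, "r")), if (ma == 0) "additive" else "product",
          class = "torusseg_degenerate_level")
  structure(list(thd = h, tvd = v,
                 t_a_norm = abs(t_a) / ma, t_p_norm = abs(t_p) / mp,
                 r = attr(freq, "r")),
            class = "torusseg_level")
}

#' @export
print.torusseg_level <- function(x, ...) {
  cat(sprintf("<torusseg_level> r = %s, %d x %d\n",
              format(x$r), nrow(x$t_a_norm), ncol(x$t_a_norm)))
  invisible(x)
}
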