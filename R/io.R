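#' Read a JPEG/PNG image as an RGB array
#'
#' Decodes a raster file into an `N x M x 3` numeric array with channel values
#' in `[0, 255]` (rows index the vertical axis, columns the horizontal axis).
#' Grayscale files are replicated to three identical channels; an alpha channel,
#' if present, is dropped.
#'
#' @param path Path to a JPEG or PNG file.
#' @return Numeric `N x M x 3` array in `[0, 255]`.
#' @seealso [rgb_to_gray()], [save_mask()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stopf("cannot read image: file not found: %s", as.character(path)[1],
          class = "torusseg_io_error")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stopf("cannot decode image %s: %s", path, conditionMessage(e),
                          class = "torusseg_io_error"))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else if (length(dim(a)) == 3L) {
    if (dim(a)[3] < 3L) a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
    else a <- a[, , 1:3, drop = FALSE]          # drop alpha
  } else {
    stopf("unsupported image layout in %s", path, class = "torusseg_io_error")
  }
  aperm(a, c(2L, 1L, 3L)) * 255                 # EBImage stores x (width) first
}

#' Write a binary mask as an 8-bit PNG
#'
#' Mask values `{0, 1}` are written as `{0, 255}` so that
#' `load_image(save_mask(m))` round-trips the mask exactly.
#'
#' @param mask Binary matrix (`0/1` or logical).
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
save_mask <- function(mask, path) {
  if (!is_binary_mask(mask))
    stopf("`mask` must be a binary 0/1 matrix", class = "torusseg_invalid_input")
  if (!dir.exists(dirname(path)))
    stopf("cannot write mask: directory does not exist: %s", path,
          class = "torusseg_io_error")
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(as_mask(mask))), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write mask to %s", path, class = "torusseg_io_error")
  invisible(path)
}

#' Convert an RGB image to grayscale amplitude
#'
#' Applies the CIE 1931 luminance combination
#' `Y = 0.2126 R + 0.7152 G + 0.0722 B` per pixel. The result is kept
#' real-valued (no 8-bit quantization): downstream transforms are continuous
#' and rounding would be an avoidable loss.
#'
#' @param img `N x M x 3` numeric array with values in `[0, 255]`.
#' @return `N x M` numeric matrix of amplitudes in `[0, 255]`.
#' @examples
#' px <- array(c(100, 0, 0), c(1, 1, 3))
#' rgb_to_gray(px)   # 21.26
#' @export
rgb_to_gray <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stopf("`img` must be an N x M x 3 array (got %s)",
          paste(dim(img), collapse = "x"), class = "torusseg_invalid_input")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stopf("channel values must lie in [0, 255]", class = "torusseg_invalid_input")
  y <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  matrix(y, dim(img)[1], dim(img)[2])
}

#' Downscale a grayscale image to a maximum side length
#'
#' Images whose longest side exceeds `max_side` are resized (bilinear) so the
#' longest side equals `max_side`; smaller images pass through untouched.
#'
#' @param gray Numeric amplitude matrix.
#' @param max_side Maximum allowed side length in pixels.
#' @return Amplitude matrix, possibly resized.
#' @export
downscale_gray <- function(gray, max_side = 1024L) {
  check_gray(gray)
  n <- nrow(gray); m <- ncol(gray)
  if (max(n, m) <= max_side) return(gray)
  s <- max_side / max(n, m)
  out <- EBImage::resize(EBImage::Image(t(gray) / 255),
                         w = max(1L, round(m * s)), h = max(1L, round(n * s)))
  pmin(pmax(t(matrix(as.numeric(out), dim(out)[1], dim(out)[2])) * 255, 0), 255)
}
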