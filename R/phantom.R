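#' Specification of a synthetic wound phantom
#'
#' Describes a wound-like RGB test image: a dark reddish elliptical lesion on
#' a lighter skin-tone background with a mild horizontal illumination
#' gradient, an optionally Gaussian-blurred lesion boundary (blurred edges are
#' typical of healing wounds), optional bright distractor disks (dressing or
#' gauze-like objects), and additive Gaussian channel noise. The ground-truth
#' mask is the unblurred ellipse raster, fixed before any degradation.
#'
#' @param height,width Image size in pixels (defaults 256).
#' @param lesion_center `(row, col)` of the ellipse center; default the image
#'   center.
#' @param lesion_axes `(a, b)` semi-axes in pixels (default `c(40, 25)`).
#' @param lesion_angle Ellipse rotation in radians (default 0).
#' @param lesion_color RGB triple of the lesion (default dark reddish
#'   `c(120, 30, 25)`, mimicking exposed tissue after debridement).
#' @param skin_color RGB triple of the background (default `c(210, 170, 150)`).
#' @param edge_blur_sigma Gaussian sigma, in pixels, applied to the lesion
#'   alpha; 0 keeps a sharp edge.
#' @param noise_sigma Additive i.i.d. Gaussian noise per channel, in gray
#'   levels.
#' @param distractors List of `list(center = c(row, col), radius, color)`
#'   disks painted over the background.
#' @param seed Integer seed making the phantom fully reproducible.
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         lesion_center = c(height / 2, width / 2),
                         lesion_axes = c(40, 25), lesion_angle = 0,
                         lesion_color = c(120, 30, 25),
                         skin_color = c(210, 170, 150),
                         edge_blur_sigma = 0, noise_sigma = 0,
                         distractors = list(), seed = 1L) {
  spec <- structure(list(height = as.integer(height), width = as.integer(width),
                         lesion_center = as.numeric(lesion_center),
                         lesion_axes = as.numeric(lesion_axes),
                         lesion_angle = lesion_angle,
                         lesion_color = lesion_color, skin_color = skin_color,
                         edge_blur_sigma = edge_blur_sigma,
                         noise_sigma = noise_sigma,
                         distractors = distractors, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]; th <- spec$lesion_angle
  ext_col <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ext_row <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  if (spec$lesion_center[1] - ext_row < 1 ||
      spec$lesion_center[1] + ext_row > spec$height ||
      spec$lesion_center[2] - ext_col < 1 ||
      spec$lesion_center[2] + ext_col > spec$width)
    stopf("lesion ellipse extends outside the %d x %d frame",
          spec$height, spec$width, class = "torusseg_invalid_spec")
  cols <- c(spec$lesion_color, spec$skin_color,
            unlist(lapply(spec$distractors, `[[`, "color")))
  if (any(cols < 0 | cols > 255))
    stopf("phantom colors must lie in [0, 255]", class = "torusseg_invalid_spec")
  spec
}

#' Generate a phantom image and its ground-truth mask
#'
#' Fully reproducible from `spec$seed`. Construction order: skin background
#' with a +/-10 percent horizontal illumination gradient; lesion ellipse composited
#' through its (optionally blurred) alpha; distractor disks painted; Gaussian
#' channel noise added and clipped to `[0, 255]`. The truth mask is rasterized
#' before blur and noise, so it is independent of both.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `"phantom_sample"`: list with `image`
#'   (`N x M x 3` array in `[0, 255]`), `truth` (binary matrix), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stopf("`spec` must be a phantom_spec", class = "torusseg_invalid_input")
  validate_phantom_spec(spec)
  n <- spec$height; m <- spec$width
  rr <- .row(c(n, m)); cc <- .col(c(n, m))
  th <- spec$lesion_angle
  xr <- (cc - spec$lesion_center[2]) * cos(th) + (rr - spec$lesion_center[1]) * sin(th)
  yr <- -(cc - spec$lesion_center[2]) * sin(th) + (rr - spec$lesion_center[1]) * cos(th)
  truth <- as_mask((xr / spec$lesion_axes[1])^2 + (yr / spec$lesion_axes[2])^2 <= 1)
  alpha <- matrix(as.numeric(truth), n, m)
  if (spec$edge_blur_sigma > 0)
    alpha <- pmin(pmax(gaussian_smooth(alpha, spec$edge_blur_sigma), 0), 1)
  grad <- 1 + 0.10 * (2 * (cc - 1) / max(m - 1, 1) - 1)
  img <- array(0, c(n, m, 3))
  with_seed(spec$seed, {
    for (k in 1:3) {
      ch <- (spec$skin_color[k] * grad) * (1 - alpha) + spec$lesion_color[k] * alpha
      for (d in spec$distractors) {
        dm <- (rr - d$center[1])^2 + (cc - d$center[2])^2 <= d$radius^2
        ch[dm] <- d$color[k]
      }
      if (spec$noise_sigma > 0) ch <- ch + rnorm(n * m, 0, spec$noise_sigma)
      img[, , k] <- pmin(pmax(ch, 0), 255)
    }
  })
  structure(list(image = img, truth = truth, spec = spec),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %d x %d, lesion %d px, blur %g, noise %g, seed %d\n",
              x$spec$height, x$spec$width, sum(x$truth),
              x$spec$edge_blur_sigma, x$spec$noise_sigma, x$spec$seed))
  invisible(x)
}

#' Seeded suite of phantoms spanning the documented difficulty ranges
#'
#' Draws `n` phantoms with semi-axes in 15--60 px, random center and
#' orientation, edge blur covering 0--8 px, channel noise covering 0--10 gray
#' levels, and 0--2 bright distractor disks. Blur and noise each cover their
#' range on an even grid (so the suite always spans sharp-to-blurred and
#' clean-to-noisy), with the pairing and all other parameters drawn under the
#' given seed; the same `(n, seed)` reproduces the identical suite anywhere.
#'
#' @param n Number of phantoms.
#' @param seed Integer master seed.
#' @param height,width Phantom size (defaults 256).
#' @return List of `n` `"phantom_sample"` objects.
#' @export
phantom_suite <- function(n = 20L, seed = 1L, height = 256L, width = 256L) {
  if (!is.finite(n) || n < 1)
    stopf("`n` must be >= 1", class = "torusseg_invalid_parameter")
  n <- as.integer(n)
  specs <- with_seed(seed, {
    blurs <- if (n == 1) 0 else seq(0, 8, length.out = n)
    noises <- if (n == 1) 0 else sample(seq(0, 10, length.out = n))
    lapply(seq_len(n), function(i) {
      a <- runif(1, 15, 60); b <- runif(1, 15, 60); th <- runif(1, 0, pi)
      ext_c <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
      ext_r <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
      ctr <- c(runif(1, ext_r + 2, height - ext_r - 1),
               runif(1, ext_c + 2, width - ext_c - 1))
      nd <- sample(0:2, 1)
      distract <- lapply(seq_len(nd), function(d) {
        dr <- runif(1, 8, 20)
        list(center = c(runif(1, dr + 1, height - dr),
                        runif(1, dr + 1, width - dr)),
             radius = dr, color = c(240, 240, 230))
      })
      phantom_spec(height = height, width = width, lesion_center = ctr,
                   lesion_axes = c(a, b), lesion_angle = th,
                   edge_blur_sigma = blurs[i], noise_sigma = noises[i],
                   distractors = distract,
                   seed = as.integer((seed * 1009L + i) %% .Machine$integer.max))
    })
  })
  lapply(specs, generate_phantom)
}
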