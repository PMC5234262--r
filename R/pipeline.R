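#' Segmentation pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline. The frequency-parameter
#' sweep (`r_min`, `r_max`, `levels`) and torus radius `R` are the published
#' operating point of the method; the refinement parameters (`morph_radius`,
#' `min_support`, `min_component_area`, `smooth_sigma`) were calibrated on the
#' phantom suite, since only the intent of the morphological step -- not its
#' operators -- is fixed by the method.
#'
#' @param r_min,r_max Frequency-parameter sweep bounds (defaults 0.013, 0.015).
#' @param levels Number of contrast levels in the sweep (default 30).
#' @param R Major torus radius in pixels (default 100).
#' @param amplitude_offset Shift mapping stored amplitudes `[0,255]` to the
#'   working range `[1,256]` (default 1).
#' @param threshold_target Field the per-level Otsu threshold is applied to,
#'   `"ta"` (additive operator, default) or `"tp"` (product operator).
#' @param bins Histogram bin count for the threshold optimizer (default 256).
#' @param morph_radius Disk radius, in pixels, of the closing element
#'   (default 5).
#' @param min_component_area Minimum surviving component area in pixels;
#'   `NULL` (default) means 0.5 percent of the image area.
#' @param min_support Minimum number of levels whose contour must pass through
#'   a pixel for it to enter the fused edge support (default 2; capped at the
#'   number of non-degenerate levels, so single-level maps are not erased).
#' @param smooth_sigma Gaussian pre-smoothing of the grayscale amplitude, in
#'   pixels; 0 disables (default 1).
#' @param component_select Rule choosing the wound among surviving components:
#'   `"darkest"` (lowest mean amplitude, default -- the ulcer is the darkest
#'   region) or `"largest"`.
#' @param max_side Images larger than this on their longest side are
#'   downscaled first (default 1024).
#' @param saturation_std Warn about channel saturation when the grayscale
#'   standard deviation falls below this many gray levels (default 2).
#' @param seed Seed recorded for provenance when the pipeline is driven from
#'   stochastic fixtures; the pipeline itself is deterministic.
#' @return Object of class `"torusseg_config"` (a named list).
#' @export
torus_config <- function(r_min = 0.013, r_max = 0.015, levels = 30L,
                         R = 100, amplitude_offset = 1,
                         threshold_target = c("ta", "tp"), bins = 256L,
                         morph_radius = 5L, min_component_area = NULL,
                         min_support = 2L, smooth_sigma = 1,
                         component_select = c("darkest", "largest"),
                         max_side = 1024L, saturation_std = 2, seed = NULL) {
  threshold_target <- match.arg(threshold_target)
  component_select <- match.arg(component_select)
  if (!is.finite(r_min) || !is.finite(r_max) || r_min <= 0 || r_min > r_max)
    stopf("need 0 < r_min <= r_max", class = "torusseg_invalid_parameter")
  if (levels < 1) stopf("`levels` must be >= 1", class = "torusseg_invalid_parameter")
  if (morph_radius < 1) stopf("`morph_radius` must be >= 1", class = "torusseg_invalid_parameter")
  if (R <= 0) stopf("torus radius `R` must be positive", class = "torusseg_invalid_parameter")
  structure(list(r_min = r_min, r_max = r_max, levels = as.integer(levels),
                 R = R, amplitude_offset = amplitude_offset,
                 threshold_target = threshold_target, bins = as.integer(bins),
                 morph_radius = as.integer(morph_radius),
                 min_component_area = min_component_area,
                 min_support = as.integer(min_support),
                 smooth_sigma = smooth_sigma,
                 component_select = component_select,
                 max_side = as.integer(max_side),
                 saturation_std = saturation_std, seed = seed),
            class = "torusseg_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file whose keys mirror the arguments of [torus_config()].
#' @return A `"torusseg_config"`.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path))
    stopf("config file not found: %s", path, class = "torusseg_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(torus_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown config keys: %s", paste(bad, collapse = ", "),
          class = "torusseg_invalid_parameter")
  do.call(torus_config, vals)
}

#' @export
print.torusseg_config <- function(x, ...) {
  cat("<torusseg_config>\n")
  cat(sprintf("  sweep: %d levels, r in [%g, %g]; torus R = %g\n",
              x$levels, x$r_min, x$r_max, x$R))
  cat(sprintf("  threshold on %s (%d bins); refine: smooth %g px, support >= %d, disk %d, select %s\n",
              toupper(x$threshold_target), x$bins, x$smooth_sigma,
              x$min_support, x$morph_radius, x$component_select))
  invisible(x)
}

#' Inner boundary of a level's Omega1 set
#'
#' A pixel is a contour pixel when it belongs to `Omega1` and at least one of
#' its 4-neighbours belongs to `Omega2`; positions outside the image frame are
#' treated as `Omega2`, so an `Omega1` region touching the border contributes
#' its border pixels.
#'
#' @param binarization A `"torusseg_binarization"`, or a bare binary matrix
#'   interpreted as `Omega1`.
#' @return Binary matrix of boundary pixels.
#' @export
extract_contours <- function(binarization) {
  m <- if (inherits(binarization, "torusseg_binarization")) binarization$omega1
       else binarization
  if (!is_binary_mask(m))
    stopf("`binarization` must be a binarization or a binary matrix",
          class = "torusseg_invalid_input")
  n <- nrow(m); k <- ncol(m)
  inside <- m != 0
  pad <- matrix(FALSE, n + 2L, k + 2L)
  pad[2:(n + 1), 2:(k + 1)] <- inside
  all4 <- pad[1:n, 2:(k + 1)] & pad[3:(n + 2), 2:(k + 1)] &
          pad[2:(n + 1), 1:k] & pad[2:(n + 1), 3:(k + 2)]
  as_mask(inside & !all4)
}

#' Accumulate level contours into an edge map
#'
#' @param contours Nonempty list of equal-shape binary contour masks.
#' @return Object of class `"torusseg_edgemap"`: list with the integer matrix
#'   `counts` (per pixel, how many levels' contours pass through it) and
#'   `levels_used`.
#' @export
fuse_levels <- function(contours) {
  if (!is.list(contours) || !length(contours))
    stopf("`contours` must be a nonempty list of masks", class = "torusseg_invalid_input")
  do.call(check_shapes, contours)
  counts <- Reduce(`+`, lapply(contours, function(m) {
    if (!is_binary_mask(m))
      stopf("contours must be binary matrices", class = "torusseg_invalid_input")
    as_mask(m)
  }))
  structure(list(counts = counts, levels_used = length(contours)),
            class = "torusseg_edgemap")
}

#' Morphological refinement of the fused edge map into the wound mask
#'
#' Edge support is taken where at least `min_support` level contours agree
#' (capped at the number of levels available), excluding the 1-pixel image
#' frame, whose boundary pixels reflect the finite frame rather than image
#' contrast. The support is closed with a disk of radius `morph_radius`, holes
#' are filled, components smaller than `min_component_area` are dropped, and
#' among the survivors the wound is selected as the component with the lowest
#' mean amplitude (`component_select = "darkest"`; the ulcer presents the
#' lowest gray-scale amplitudes) or the largest one.
#'
#' @param edges A `"torusseg_edgemap"` from [fuse_levels()].
#' @param gray Amplitude matrix of the image being segmented (used for the
#'   darkness selection rule).
#' @param config A [torus_config()].
#' @return List with `mask` (binary matrix; all zeros when nothing survives),
#'   `empty` flag, and `components`, a tibble of surviving candidate
#'   components (label, area, mean amplitude, selected).
#' @export
morphological_refine <- function(edges, gray, config = torus_config()) {
  if (!inherits(edges, "torusseg_edgemap"))
    stopf("`edges` must be a torusseg_edgemap", class = "torusseg_invalid_input")
  check_gray(gray)
  check_shapes(edges$counts, gray)
  n <- nrow(gray); m <- ncol(gray)
  support_min <- max(1L, min(config$min_support, edges$levels_used))
  support <- edges$counts >= support_min
  support[c(1L, n), ] <- FALSE
  support[, c(1L, m)] <- FALSE
  empty_result <- function() list(
    mask = matrix(0L, n, m), empty = TRUE,
    components = tibble::tibble(label = integer(), area = integer(),
                                mean_amplitude = numeric(), selected = logical()))
  if (!any(support)) return(empty_result())
  kern <- EBImage::makeBrush(2L * config$morph_radius + 1L, shape = "disc")
  closed <- EBImage::closing(matrix(as.numeric(support), n, m), kern)
  filled <- EBImage::fillHull(closed)
  labels <- EBImage::bwlabel(filled)
  labels <- matrix(as.integer(labels), n, m)
  areas <- tabulate(labels[labels > 0L])
  min_area <- if (is.null(config$min_component_area)) 0.005 * n * m
              else config$min_component_area
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty_result())
  means <- vapply(keep, function(k) mean(gray[labels == k]), 0)
  sel <- if (config$component_select == "darkest") keep[which.min(means)]
         else keep[which.max(areas[keep])]
  list(mask = as_mask(labels == sel), empty = FALSE,
       components = tibble::tibble(label = keep, area = areas[keep],
                                   mean_amplitude = means,
                                   selected = keep == sel))
}

#' Segment a wound photograph
#'
#' Runs the full pipeline: grayscale conversion, optional downscaling and
#' smoothing, the frequency-parameter sweep, per-level toroidal decomposition
#' and Otsu binarization, contour extraction and fusion, and morphological
#' refinement. The computation is deterministic: identical pixels and
#' configuration always give identical results, and each level is processed
#' independently of the others.
#'
#' Degenerate levels (zero operator or single-bin histogram) are skipped and
#' recorded in the per-level diagnostics. A constant-amplitude image has no
#' contrast to decompose -- its frequency field is constant and every level's
#' partition would be independent of the image -- so all levels are declared
#' degenerate and an error of class `"torusseg_all_levels_degenerate"` is
#' raised. A near-constant (saturated) image only triggers a warning of class
#' `"torusseg_saturation_warning"`.
#'
#' @param img RGB array (`N x M x 3`, values in `[0, 255]`), e.g. from
#'   [load_image()] or [generate_phantom()].
#' @param config A [torus_config()].
#' @return Object of class `"torusseg_segmentation"`: list with `mask` (binary
#'   wound mask), `empty` flag, `edge_map`, `per_level` diagnostics tibble
#'   (level, r, skipped, reason, threshold bin and value, objective J, Omega1
#'   area), `components`, the processed `gray` amplitude, and the `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' res <- segment(ph$image, torus_config())
#' image_correlation(res$mask, ph$truth)
#' @export
segment <- function(img, config = torus_config()) {
  gray <- rgb_to_gray(img)
  gray <- downscale_gray(gray, config$max_side)
  if (sd(gray) < config$saturation_std && sd(gray) > 0)
    warning(warningCondition(
      sprintf("image is nearly constant (amplitude sd %.3g < %.3g): channels may be saturated; segmentation is unreliable",
              sd(gray), config$saturation_std),
      class = "torusseg_saturation_warning"))
  gray_proc <- gaussian_smooth(gray, config$smooth_sigma)
  rs <- r_grid(config$r_min, config$r_max, config$levels)
  n_lev <- length(rs)
  diag_row <- function(i, r, skipped, reason, thr = NULL, area = NA_integer_)
    tibble::tibble(level = i, r = r, skipped = skipped, reason = reason,
                   t = if (is.null(thr)) NA_integer_ else thr$t,
                   t_value = if (is.null(thr)) NA_real_ else thr$t_value,
                   J = if (is.null(thr)) NA_real_ else thr$J,
                   omega1_area = area)
  if (sd(gray) == 0) {
    per_level <- do.call(rbind, lapply(seq_len(n_lev), function(i)
      diag_row(i, rs[i], TRUE, "constant amplitude: no contrast to decompose")))
    stop(errorCondition(
      sprintf("all %d levels degenerate (constant-amplitude image); config: %d levels, r in [%g, %g]",
              n_lev, config$levels, config$r_min, config$r_max),
      class = c("torusseg_all_levels_degenerate", "torusseg_error"),
      per_level = per_level))
  }
  grids <- make_grids(nrow(gray_proc), ncol(gray_proc))
  contours <- vector("list", n_lev)
  rows <- vector("list", n_lev)
  for (i in seq_len(n_lev)) {
    res <- tryCatch({
      freq <- synthetic_frequency(gray_proc, rs[i], config$amplitude_offset)
      level <- toroidal_operators(gray_proc, grids, freq,
                                  R = config$R,
                                  amplitude_offset = config$amplitude_offset)
      binarize_level(level, bins = config$bins, target = config$threshold_target)
    }, torusseg_degenerate_level = function(e) e,
       torusseg_degenerate_histogram = function(e) e)
    if (inherits(res, "condition")) {
      rows[[i]] <- diag_row(i, rs[i], TRUE, conditionMessage(res))
    } else {
      contours[[i]] <- extract_contours(res)
      rows[[i]] <- diag_row(i, rs[i], FALSE, NA_character_, res$threshold,
                            sum(res$omega1))
    }
  }
  per_level <- do.call(rbind, rows)
  ok <- !vapply(contours, is.null, TRUE)
  if (!any(ok))
    stop(errorCondition(
      sprintf("all %d levels degenerate; config: %d levels, r in [%g, %g]",
              n_lev, config$levels, config$r_min, config$r_max),
      class = c("torusseg_all_levels_degenerate", "torusseg_error"),
      per_level = per_level))
  edge_map <- fuse_levels(contours[ok])
  refined <- morphological_refine(edge_map, gray_proc, config)
  structure(list(mask = refined$mask, empty = refined$empty,
                 edge_map = edge_map, per_level = per_level,
                 components = refined$components,
                 gray = gray, config = config),
            class = "torusseg_segmentation")
}

#' @export
print.torusseg_segmentation <- function(x, ...) {
  cat(sprintf("<torusseg_segmentation> %d x %d\n", nrow(x$gray), ncol(x$gray)))
  cat(sprintf("  levels: %d used, %d skipped\n",
              x$edge_map$levels_used, sum(x$per_level$skipped)))
  if (x$empty) cat("  mask: empty (no component survived refinement)\n")
  else cat(sprintf("  mask: %d px (%.1f%% of image)\n", sum(x$mask),
                   100 * mean(x$mask)))
  invisible(x)
}

#' Plot a segmentation result
#'
#' Renders the grayscale image with the mask contour overlaid.
#'
#' @param x A `"torusseg_segmentation"`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.torusseg_segmentation <- function(x, ...) {
  n <- nrow(x$gray); m <- ncol(x$gray)
  graphics::image(t(x$gray)[, n:1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = n / m, useRaster = TRUE)
  if (!x$empty) {
    ring <- which(extract_contours(x$mask) == 1L, arr.ind = TRUE)
    graphics::points((ring[, 2] - 1) / (m - 1), 1 - (ring[, 1] - 1) / (n - 1),
                     pch = ".", col = "red")
  }
  invisible(x)
}
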