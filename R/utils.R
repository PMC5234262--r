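stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "torusseg_error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_binary_mask <- function(x) {
  is.matrix(x) && all(x %in% c(0, 1, FALSE, TRUE))
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

check_gray <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || !is.numeric(gray))
    stopf("`%s` must be a numeric matrix", arg, class = "torusseg_invalid_input")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    stopf("`%s` must contain amplitudes in [0, 255] without NAs", arg,
          class = "torusseg_invalid_input")
  invisible(gray)
}

# Gaussian smoothing with a kernel clamped to the image size (EBImage's
# filter2 requires kernel <= image). Replicate boundary so edges stay flat.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  side <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  side <- min(side, 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L)
  if (side < 3L) return(x)
  kern <- EBImage::makeBrush(side, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(x, kern, boundary = "replicate")
  matrix(as.numeric(out), nrow(x), ncol(x))
}
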