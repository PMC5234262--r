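test_that("histograms bin [0,1] values with a right-closed last bin", {
  h <- gray_histogram(matrix(0, 4, 4), bins = 8)
  expect_equal(h$probs, c(1, rep(0, 7)))
  h2 <- gray_histogram(matrix(c(0, 0, 1, 1), 2), bins = 2)
  expect_equal(h2$probs, c(0.5, 0.5))
  ramp <- matrix((0:255) / 255, 16, 16)
  h3 <- gray_histogram(ramp, bins = 256)
  expect_equal(h3$probs, rep(1 / 256, 256))
  expect_equal(sum(h3$probs), 1, tolerance = 1e-9)
  expect_error(gray_histogram(matrix(c(0, 1.2), 1)), class = "torusseg_invalid_input")
  expect_error(gray_histogram(matrix(0.5), bins = 1), class = "torusseg_invalid_parameter")
})

test_that("the symmetric two-point histogram gives the forced objective and smallest tie", {
  p <- numeric(256); p[1] <- 0.5; p[256] <- 0.5   # mass at levels 0 and 255
  res <- otsu_threshold(p)
  expect_equal(res$t, 1L)                          # every t separates; smallest wins
  expect_equal(res$J, 127.5^2)
  expect_equal(res$class_means, c(mu0 = 0, mu1 = 255))
  expect_equal(res$class_weights, c(w0 = 0.5, w1 = 0.5))
})

test_that("a constant image yields the degenerate-histogram error", {
  expect_error(otsu_threshold(gray_histogram(matrix(0.42, 5, 5))),
               class = "torusseg_degenerate_histogram")
})

test_that("otsu matches the exhaustive brute-force scan on 100 random histograms", {
  with_seed_test(2024, {
    for (k in 1:100) {
      p <- random_histogram(256)
      got <- otsu_threshold(p)
      oracle <- brute_force_otsu(p)
      expect_otsu_matches_oracle(got, oracle)
      # mixture identities
      expect_equal(sum(got$class_weights), 1, tolerance = 1e-9)
      expect_equal(sum(got$class_weights * got$class_means), got$global_mean,
                   tolerance = 1e-9)
      expect_gte(got$J, 0)
    }
  })
})

test_that("scaling mass positions scales means linearly and J quadratically", {
  # moving all mass from bins i to bins 2i doubles the level values
  p <- numeric(256); p[c(11, 41, 91)] <- c(0.3, 0.5, 0.2)
  p2 <- numeric(256); p2[c(21, 81, 181)] <- c(0.3, 0.5, 0.2)
  a <- otsu_threshold(p); b <- otsu_threshold(p2)
  expect_equal(b$global_mean, 2 * a$global_mean, tolerance = 1e-9)
  expect_equal(unname(b$class_means), 2 * unname(a$class_means), tolerance = 1e-9)
  expect_equal(b$J, 4 * a$J, tolerance = 1e-9)
})

make_level <- function(t_a, t_p, r = 0.014) {
  structure(list(thd = t_a * 0, tvd = t_a * 0, t_a_norm = t_a, t_p_norm = t_p,
                 r = r), class = "torusseg_level")
}

test_that("level binarization partitions pixels and separates modes", {
  # bimodal field thresholded against itself: omega1 = low mode
  vals <- with_seed_test(9, matrix(c(runif(40, 0, 0.2), runif(24, 0.8, 1)), 8, 8))
  vals[which.max(vals)] <- 1                      # normalized fields attain 1
  bin <- binarize_level(make_level(vals, vals))
  low <- matrix(as.integer(vals <= bin$threshold$t_value), 8, 8)
  expect_equal(bin$omega1, low)
  expect_true(all((vals <= 0.2) == (bin$omega1 == 1)))
  # partition contract: disjoint, covering
  expect_true(all(bin$omega1 + bin$omega2 == 1))

  # random seeded levels keep the partition contract with cross-application
  for (s in 1:5) {
    ta <- with_seed_test(s, matrix(runif(100), 10, 10)); ta[1] <- 1
    tp <- with_seed_test(s + 50, matrix(runif(100), 10, 10)); tp[100] <- 1
    b2 <- binarize_level(make_level(ta, tp))
    expect_true(all(b2$omega1 + b2$omega2 == 1))
    expect_true(all(b2$omega1 * b2$omega2 == 0))
    # threshold is optimized on the product operator's histogram
    expect_otsu_matches_oracle(b2$threshold,
                               brute_force_otsu(gray_histogram(tp, 256)$probs))
  }
})

test_that("on a phantom level the lesion falls preferentially into the dark class", {
  ph <- generate_phantom(phantom_spec(seed = 33, edge_blur_sigma = 1, noise_sigma = 3))
  gray <- rgb_to_gray(ph$image)
  grids <- make_grids(nrow(gray), ncol(gray))
  freq <- synthetic_frequency(gray, 0.014)
  lev <- toroidal_operators(gray, grids, freq, R = 100)
  bin <- binarize_level(lev)
  lesion <- ph$truth == 1
  expect_gt(mean(bin$omega1[lesion]), mean(bin$omega1[!lesion]))
})
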