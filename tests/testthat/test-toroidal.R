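test_that("coordinate grids are symmetric inclusive ramps", {
  g <- make_grids(3, 2)
  expect_equal(g$u[1, ], c(-0.5, 0.5))
  expect_equal(g$u, matrix(c(-0.5, 0.5), 3, 2, byrow = TRUE))
  g3 <- make_grids(2, 3)
  expect_equal(g3$u[1, ], c(-2 / 3, 0, 2 / 3))
  expect_equal(g3$v[, 1], c(-0.5, 0.5))
  g1 <- make_grids(1, 1)
  expect_equal(g1$u, matrix(0))
  expect_equal(g1$v, matrix(0))
  # symmetric about zero, inside [-1, 1], constant along the other axis
  gg <- make_grids(7, 10)
  expect_equal(gg$u, -gg$u[, 10:1])
  expect_true(all(abs(gg$u) <= 1) && all(abs(gg$v) <= 1))
  expect_equal(gg$u[1, ], gg$u[7, ])
  expect_equal(gg$v[, 1], gg$v[, 10])
  expect_error(make_grids(0, 5), class = "torusseg_invalid_parameter")
})

test_that("toroidal maps match frozen high-precision evaluations and their limits", {
  grids <- list(u = matrix(0.25), v = matrix(0))
  f1 <- matrix(1); attr(f1, "r") <- 1
  expect_equal(thd(grids, f1, R = 100)[1, 1], 22.0584040749698, tolerance = 1e-12)
  expect_equal(tvd(grids, f1, R = 100)[1, 1], -98.5121651804468, tolerance = 1e-12)
  # f -> 0+ at u = v = 0: THD -> R + 1, TVD -> 0
  g0 <- list(u = matrix(0), v = matrix(0))
  f0 <- matrix(1e-12)
  expect_equal(thd(g0, f0, R = 100)[1, 1], 101, tolerance = 1e-9)
  expect_equal(tvd(g0, f0, R = 100)[1, 1], 0, tolerance = 1e-9)
  # periodicity of the u-dependence: u and u + 1/f give the same THD
  f <- matrix(0.7)
  expect_equal(thd(list(u = matrix(0.2)), f, 100),
               thd(list(u = matrix(0.2 + 1 / 0.7)), f, 100), tolerance = 1e-9)
  expect_error(thd(make_grids(2, 2), matrix(1, 3, 3)), class = "torusseg_invalid_input")
})

test_that("operators match an independent scalar oracle on random tuples", {
  with_seed_test(101, {
    n_tuples <- 1000
    amp <- runif(n_tuples, 1, 256)
    u <- runif(n_tuples, -1, 1)
    v <- runif(n_tuples, -1, 1)
    r <- runif(n_tuples, 0.001, 1)
    R <- runif(n_tuples, 1, 200)
    for (i in seq_len(n_tuples)) {
      o <- scalar_toroidal(amp[i], u[i], v[i], r[i], R[i])
      grids <- list(u = matrix(u[i]), v = matrix(v[i]))
      freq <- synthetic_frequency(matrix(amp[i] - 1), r[i])
      expect_equal(freq[1, 1], o$f, tolerance = 1e-9)
      expect_equal(thd(grids, freq, R[i])[1, 1], o$thd, tolerance = 1e-9)
      expect_equal(tvd(grids, freq, R[i])[1, 1], o$tvd, tolerance = 1e-9)
    }
  })
})

test_that("a 1x1 level reproduces the step-by-step scalar operator oracle", {
  o <- scalar_toroidal(2, 0, 0, 1, 100)          # A~ = 2, f = 1/2
  grids <- make_grids(1, 1)
  freq <- synthetic_frequency(matrix(1), 1)      # stored 1 -> A~ = 2
  expect_equal(freq[1, 1], 0.5)
  lev <- toroidal_operators(matrix(1), grids, freq, R = 100)
  # frozen independent evaluation of T_a and T_p before normalization
  expect_equal(o$t_a, -151.015194271864, tolerance = 1e-10)
  expect_equal(o$t_p, -8999.20554951557, tolerance = 1e-10)
  expect_equal(lev$t_a_norm[1, 1], 1)            # |T|/max|T| of a scalar
  expect_equal(lev$t_p_norm[1, 1], 1)
  expect_equal(lev$thd[1, 1], o$thd, tolerance = 1e-12)
  expect_equal(lev$tvd[1, 1], o$tvd, tolerance = 1e-12)
})

test_that("normalized operators live on [0,1] with max 1 and respect the amplitude bound", {
  gray <- with_seed_test(7, matrix(runif(30 * 20, 0, 255), 30, 20))
  grids <- make_grids(30, 20)
  for (r in c(0.013, 0.015, 0.3)) {
    freq <- synthetic_frequency(gray, r)
    lev <- toroidal_operators(gray, grids, freq, R = 100)
    for (tn in list(lev$t_a_norm, lev$t_p_norm)) {
      expect_true(all(tn >= 0 & tn <= 1))
      expect_equal(max(tn), 1)
    }
    amp_max <- max(gray) + 1
    t_a <- (gray + 1) * (lev$tvd + lev$thd)
    t_p <- (gray + 1)^2 * (lev$tvd * lev$thd)
    expect_true(all(abs(t_a) <= amp_max * 2 * 101 + 1e-9))
    expect_true(all(abs(t_p) <= amp_max^2 * 101^2 + 1e-9))
  }
})

test_that("the decomposition is strictly per pixel: joint permutations commute", {
  with_seed_test(21, {
    gray <- matrix(runif(48, 0, 255), 6, 8)
    grids <- make_grids(6, 8)
    freq <- synthetic_frequency(gray, 0.014)
    lev <- toroidal_operators(gray, grids, freq, R = 100)
    perm <- sample(48)
    pm <- function(m) matrix(as.numeric(m)[perm], 6, 8)
    grids_p <- list(u = pm(grids$u), v = pm(grids$v))
    freq_p <- synthetic_frequency(pm(gray), 0.014)
    lev_p <- toroidal_operators(pm(gray), grids_p, freq_p, R = 100)
    expect_equal(lev_p$t_a_norm, pm(lev$t_a_norm), tolerance = 1e-12)
    expect_equal(lev_p$t_p_norm, pm(lev$t_p_norm), tolerance = 1e-12)
  })
})

test_that("an annihilated operator raises the degenerate-level error", {
  # amplitude_offset 0 with a stored all-zero image kills the Hadamard factor
  gray <- matrix(0, 4, 4)
  grids <- make_grids(4, 4)
  freq <- structure(matrix(1, 4, 4), r = 0.014)
  expect_error(toroidal_operators(gray, grids, freq, R = 100, amplitude_offset = 0),
               class = "torusseg_degenerate_level")
})
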