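test_that("peak_max refines interior peaks by the parabolic vertex", {
  s <- gaussian_spectrum(center = 345, sigma = 12)
  pk <- peak_max(s)
  expect_true(pk$interpolated)
  expect_equal(pk$x_at_max, 345, tolerance = 0.01 / 345)

  # off-grid centre: the vertex lands between samples
  pk2 <- peak_max(gaussian_spectrum(center = 345.4, sigma = 12))
  expect_equal(pk2$x_at_max, 345.4, tolerance = 0.05 / 345)
})

test_that("peak_max is invariant to intensity scaling and offsets", {
  s <- gaussian_spectrum(center = 331.2)
  ref <- peak_max(s)$x_at_max
  for (tf in list(function(y) 7.3 * y, function(y) y + 123,
                  function(y) 0.001 * y + 5)) {
    s2 <- spectrum(s$kind, s$x, tf(s$y))
    expect_equal(peak_max(s2)$x_at_max, ref, tolerance = 1e-12)
  }
})

test_that("peak_max handles boundaries, windows and degenerate input", {
  s <- spectrum("emission", 300:320, seq(1, 2, length.out = 21))
  pk <- peak_max(s)
  expect_equal(pk$x_at_max, 320)
  expect_false(pk$interpolated)

  expect_error(peak_max(spectrum("emission", 300:320, rep(1, 21))),
               "degenerate")
  expect_error(peak_max(gaussian_spectrum(), window = c(250, 251.5)),
               "at least 3")

  # window restricted to a secondary feature finds that feature
  grid <- seq(250, 600, 1)
  two <- spectrum("emission", grid,
                  exp(-(grid - 345)^2 / 200) + 0.5 * exp(-(grid - 500)^2 / 200))
  expect_equal(peak_max(two, window = c(450, 550))$x_at_max, 500,
               tolerance = 1e-6)
})

test_that("band_shift reproduces the emission blue shift and amide-I shift", {
  expect_equal(band_shift(gaussian_spectrum(center = 345),
                          gaussian_spectrum(center = 331)),
               -14, tolerance = 0.05 / 14)
  ir_grid <- seq(1500, 1750, 1)
  a <- gaussian_spectrum("ir", ir_grid, center = 1636, sigma = 20)
  b <- gaussian_spectrum("ir", ir_grid, center = 1638, sigma = 20)
  expect_equal(band_shift(a, b), 2, tolerance = 0.1 / 2)

  s <- gaussian_spectrum(center = 345)
  expect_identical(band_shift(s, s), 0)
  expect_error(band_shift(s, a), "same kind")
})

test_that("band_shift is antisymmetric", {
  set.seed(42)
  for (k in 1:10) {
    c1 <- runif(1, 300, 380); c2 <- runif(1, 300, 380)
    a <- gaussian_spectrum(center = c1, sigma = runif(1, 8, 20))
    b <- gaussian_spectrum(center = c2, sigma = runif(1, 8, 20))
    expect_equal(band_shift(a, b), -band_shift(b, a), tolerance = 1e-12)
  }
})

test_that("synchronous_scan extracts offset diagonals with interpolation", {
  # delta 0 on a square EEM is exactly the matrix diagonal
  set.seed(7)
  g <- seq(250, 270, 5)
  z <- matrix(runif(25), 5, 5)
  e <- eem(g, g, z)
  expect_equal(synchronous_scan(e, 0)$y, diag(z), tolerance = 0)

  # 3x3 grids, delta 5: the super-diagonal, third excitation dropped
  g3 <- c(250, 255, 260)
  z3 <- matrix(runif(9), 3, 3)
  e3 <- eem(g3, g3, z3)
  s <- synchronous_scan(e3, 5)
  expect_equal(s$x, c(250, 255))
  expect_equal(s$y, c(z3[1, 2], z3[2, 3]), tolerance = 0)

  # off-grid offsets interpolate linearly along the emission axis
  s2 <- synchronous_scan(e3, 2.5)
  expect_equal(s2$y[1], (z3[1, 1] + z3[1, 2]) / 2, tolerance = 1e-12)

  expect_error(synchronous_scan(e3, 500), "emission grid")
})

test_that("synchronous scans of a Trp-like EEM cover both study channels", {
  e <- simulate_eem(data.frame(ex = 280, em = 340, height = 100, sigma = 15),
                    ex_nm = seq(240, 330, 2), em_nm = seq(250, 420, 2))
  for (delta in c(15, 60)) {
    s <- synchronous_scan(e, delta)
    expect_s3_class(s, "spectrum")
    expect_identical(s$kind, "synchronous")
    expect_gt(length(s$x), 3)
  }
})

test_that("eem_peaks finds injected blobs under scatter masking", {
  one <- simulate_eem(data.frame(ex = 280, em = 340, height = 100, sigma = 15),
                      scatter = TRUE)
  pk <- eem_peaks(one)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$ex_nm, 280)
  expect_equal(pk$em_nm, 340)

  flat <- simulate_eem(data.frame(ex = numeric(0), em = numeric(0),
                                  height = numeric(0), sigma = numeric(0)))
  expect_equal(nrow(eem_peaks(flat)), 0L)

  two <- simulate_eem(data.frame(ex = c(280, 240), em = c(340, 330),
                                 height = c(100, 60), sigma = c(12, 12)))
  pk2 <- eem_peaks(two)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$ex_nm, c(280, 240))   # intensity-ordered
  expect_equal(pk2$em_nm, c(340, 330))
})

test_that("eem_peaks equals the brute-force enumeration on random EEMs", {
  set.seed(11)
  for (k in 1:5) {
    e <- eem(ex_nm = seq(230, 325, 5), em_nm = seq(280, 375, 5),
             z = matrix(runif(20 * 20), 20, 20))
    got <- eem_peaks(e)
    want <- eem_peaks_oracle(e)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$intensity, want$intensity, tolerance = 0)
    expect_equal(got$ex_nm, want$ex_nm)
    expect_equal(got$em_nm, want$em_nm)
  }
})

test_that("absorbance_trend classifies hypo-, hyper- and no change", {
  grid <- seq(240, 320, 1)
  make <- function(scale) {
    spectrum("absorbance", grid, scale * 0.5 * exp(-(grid - 280)^2 / 450))
  }
  down <- lapply(seq(1, 0.7, length.out = 5), make)
  up <- lapply(seq(0.7, 1, length.out = 5), make)
  flat <- lapply(rep(1, 3), make)
  expect_identical(absorbance_trend(down), "hypochromic")
  expect_identical(absorbance_trend(up), "hyperchromic")
  expect_identical(absorbance_trend(flat), "none")
  expect_error(absorbance_trend(down, probe_nm = 1000), "outside")
})
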