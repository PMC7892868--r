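test_that("truth_params validates model/parameter combinations", {
  expect_error(truth_params("dynamic"), "requires `ksv_Minv`")
  expect_error(truth_params("hill_binding", kb_Minv = 1e4), "n_sites")
  expect_error(truth_params("dynamic", ksv_Minv = 5e4, kb_Minv = 1e4),
               "does not use")
  expect_error(truth_params("dynamic", ksv_Minv = 5e4,
                            noise_rel_sigma = 0.5), "noise_rel_sigma")
})

test_that("noiseless titrations satisfy their defining equations exactly", {
  q <- study_design()$q_grid_M
  f0 <- 1000

  ts <- simulate_titration(truth_params("dynamic", ksv_Minv = 5e4, f0 = f0))
  expect_equal(f0 / ts$points$F, 1 + 5e4 * q, tolerance = 1e-14)
  # single-point check from the closed form: Q = 20 uM gives F0/F = 2
  ts20 <- simulate_titration(truth_params("dynamic", ksv_Minv = 5e4, f0 = f0),
                             q_grid = c(0, 5e-6, 1e-5, 2e-5, 4e-5))
  expect_equal(f0 / ts20$points$F[4], 2, tolerance = 1e-15)

  ts0 <- simulate_titration(truth_params("dynamic", ksv_Minv = 0, f0 = f0))
  expect_true(all(ts0$points$F == f0))

  ts_st <- simulate_titration(truth_params("static", ka_Minv = 3e4, f0 = f0))
  expect_equal(f0 / ts_st$points$F, 1 + 3e4 * q, tolerance = 1e-14)

  ts_cb <- simulate_titration(truth_params("combined", ksv_Minv = 2e4,
                                           ka_Minv = 1e4, f0 = f0))
  expect_equal(f0 / ts_cb$points$F, (1 + 2e4 * q) * (1 + 1e4 * q),
               tolerance = 1e-14)

  ts_h <- simulate_titration(truth_params("hill_binding", kb_Minv = 1.6e4,
                                          n_sites = 1.1, f0 = f0))
  expect_equal((f0 - ts_h$points$F) / ts_h$points$F, 1.6e4 * q^1.1,
               tolerance = 1e-14)
})

test_that("generators are bit-reproducible given (params, seed)", {
  p <- truth_params("dynamic", ksv_Minv = 5e4, noise_rel_sigma = 0.05,
                    seed = 99L)
  expect_identical(simulate_titration(p)$points, simulate_titration(p)$points)
  p2 <- truth_params("dynamic", ksv_Minv = 5e4, noise_rel_sigma = 0.05,
                     seed = 100L)
  expect_false(identical(simulate_titration(p)$points,
                         simulate_titration(p2)$points))

  e1 <- simulate_eem(data.frame(ex = 280, em = 340, height = 10, sigma = 12),
                     noise_rel_sigma = 0.05, seed = 3L)
  e2 <- simulate_eem(data.frame(ex = 280, em = 340, height = 10, sigma = 12),
                     noise_rel_sigma = 0.05, seed = 3L)
  expect_identical(e1$z, e2$z)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_titration(truth_params("dynamic", ksv_Minv = 5e4,
                                            noise_rel_sigma = 0.01,
                                            seed = 7L)))
  expect_identical(.Random.seed, before)
})

test_that("hill-model truth is recovered by the double-log fit to 6 digits", {
  for (tr in list(c(1.60e4, 1.1), c(1e3, 0.8))) {
    p <- truth_params("hill_binding", kb_Minv = tr[1], n_sites = tr[2])
    fit <- double_log_fit(simulate_titration(p))
    expect_equal(fit$kb_Minv, tr[1], tolerance = 1e-6)
    expect_equal(fit$n_sites, tr[2], tolerance = 1e-6)
  }
})

test_that("simulated emission spectra shift from 345 to 331 nm with quenching", {
  p <- truth_params("dynamic", ksv_Minv = 4.95e4)
  s0 <- simulate_emission_spectrum(p, 0)
  expect_equal(peak_max(s0, c(300, 400))$x_at_max, 345, tolerance = 1e-6)

  s_top <- simulate_emission_spectrum(p, 1.28e-4)
  expect_equal(band_shift(s0, s_top, c(300, 400)), -14,
               tolerance = 0.05 / 14)

  # band height equals the shared-kernel model intensity: exact at Q = 0
  # (on-grid centre), within refinement accuracy off-grid
  expect_equal(max(s0$y), 1000, tolerance = 1e-15)
  ts <- simulate_titration(p)
  q <- 1.6e-5
  s <- simulate_emission_spectrum(p, q)
  expect_equal(peak_max(s, c(300, 400))$y_at_max,
               ts$points$F[ts$points$Q_molar == q], tolerance = 1e-4)

  expect_error(simulate_emission_spectrum(p, 0, grid = seq(340, 360, 1)),
               "cover")
})

test_that("simulate_kb_series matches the closed form and inverts exactly", {
  flat <- thermo_truth(0, 0, c(298, 303, 308))
  expect_true(all(simulate_kb_series(flat)$kb_Minv == 1))

  t1 <- thermo_truth(4500, 95, c(298, 303, 308, 318))
  kb <- simulate_kb_series(t1)
  want_298 <- 10^(-4500 / (2.303 * 8.314 * 298) + 95 / (2.303 * 8.314))
  expect_equal(kb$kb_Minv[1], want_298, tolerance = 1e-14)

  fit <- vant_hoff_fit(kb)
  expect_equal(fit$dH_J_per_mol, 4500, tolerance = 1e-10)
  expect_equal(fit$dS_J_per_mol_K, 95, tolerance = 1e-10)
})

test_that("simulated CD spectra hit the helix formula endpoints", {
  expect_equal(cd_estimate(simulate_cd_spectrum(0))$mre_208, -4000,
               tolerance = 1e-9)
  expect_equal(cd_estimate(simulate_cd_spectrum(100))$mre_208, -33000,
               tolerance = 1e-9)
  expect_error(simulate_cd_spectrum(101), "helix_percent")
})
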