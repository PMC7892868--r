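test_that("stern_volmer_fit recovers exact dynamic data perfectly", {
  ts <- simulate_titration(truth_params("dynamic", ksv_Minv = 5e4))
  fit <- stern_volmer_fit(ts)
  expect_equal(fit$ksv_Minv, 5e4, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$kq_Minv_s, fit$ksv_Minv / fit$tau0_s, tolerance = 0)
})

test_that("degenerate and inverted titrations are flagged, not errors", {
  q <- study_design()$q_grid_M
  flat <- titration_series(Q = q, F = rep(1000, length(q)))
  fit <- stern_volmer_fit(flat)
  expect_identical(fit$flag, "degenerate")
  expect_equal(fit$ksv_Minv, 0)

  rising <- titration_series(Q = q, F = 1000 + seq_along(q) * 10)
  expect_identical(stern_volmer_fit(rising)$flag, "negative_slope")
})

test_that("bimolecular_rate reproduces the reference Kq column", {
  ksv <- c(4.95, 5.02, 5.53, 6.16) * 1e4
  expect_identical(bimolecular_rate(ksv, 1e-8), ksv * 1e8)
  expect_equal(bimolecular_rate(4.95e4, 1e-8), 4.95e12)
  expect_equal(bimolecular_rate(6.16e4, 1e-8), 6.16e12)
  expect_identical(bimolecular_rate(0, 1e-8), 0)
  expect_error(bimolecular_rate(1e4, 0), "tau0_s")
})

test_that("kq * tau0 == ksv holds in every fit", {
  set.seed(5)
  for (k in 1:10) {
    p <- truth_params("dynamic", ksv_Minv = runif(1, 1e3, 1e5),
                      noise_rel_sigma = 0.03, seed = k)
    tau <- 10^runif(1, -9, -7)
    fit <- stern_volmer_fit(simulate_titration(p), tau0_s = tau)
    expect_equal(fit$kq_Minv_s * fit$tau0_s, fit$ksv_Minv, tolerance = 1e-12)
  }
})

test_that("Ksv scales correctly under rescaling of F and Q", {
  q <- study_design()$q_grid_M
  ts <- simulate_titration(truth_params("dynamic", ksv_Minv = 5e4,
                                        noise_rel_sigma = 0.01, seed = 2L))
  ref <- stern_volmer_fit(ts)$ksv_Minv

  scaled_f <- titration_series(Q = q, F = 37 * ts$points$F)
  expect_equal(stern_volmer_fit(scaled_f)$ksv_Minv, ref, tolerance = 1e-12)

  scaled_q <- titration_series(Q = 10 * q, F = ts$points$F)
  expect_equal(stern_volmer_fit(scaled_q)$ksv_Minv, ref / 10,
               tolerance = 1e-12)
})

test_that("OLS in the fits matches the normal-equations oracle", {
  set.seed(31)
  for (k in 1:8) {
    q <- sort(c(0, runif(6, 1e-6, 2e-4)))
    f <- 1000 / (1 + runif(1, 1e3, 1e5) * q) * (1 + rnorm(7, 0, 0.02))
    ts <- titration_series(Q = q, F = f)
    fit <- stern_volmer_fit(ts)
    want <- ols_oracle(q, f[1] / f)
    expect_equal(fit$ksv_Minv, want$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(fit$r2, want$r2, tolerance = 1e-10)

    dl <- suppressWarnings(double_log_fit(ts))
    keep <- q > 0 & f < f[1]
    want_dl <- ols_oracle(log10(q[keep]), log10((f[1] - f[keep]) / f[keep]))
    expect_equal(dl$n_sites, want_dl$slope, tolerance = 1e-10)
    expect_equal(dl$kb_Minv, 10^want_dl$intercept, tolerance = 1e-10)
  }
})

test_that("classify_mechanism applies the temperature-trend rule", {
  fits <- data.frame(temperature_K = c(298, 303, 308, 318),
                     ksv_Minv = c(4.95, 5.02, 5.53, 6.16) * 1e4)
  expect_identical(classify_mechanism(fits)$label, "dynamic")

  rev_fits <- data.frame(temperature_K = c(298, 303, 308, 318),
                         ksv_Minv = rev(fits$ksv_Minv))
  expect_identical(classify_mechanism(rev_fits)$label, "static")

  const <- transform(fits, ksv_Minv = 5e4)
  expect_identical(classify_mechanism(const)$label, "indeterminate")

  expect_error(classify_mechanism(rbind(fits, fits[1, ])), "duplicate")
  expect_error(classify_mechanism(fits[1:2, ]), ">= 3")
})

test_that("reversing a Ksv series flips dynamic and static calls", {
  set.seed(17)
  for (k in 1:10) {
    ks <- sort(runif(4, 1e4, 1e5)) * c(1, 1.05, 1.1, 1.2)
    tab <- data.frame(temperature_K = c(298, 303, 308, 318),
                      ksv_Minv = sort(ks))
    fwd <- classify_mechanism(tab)$label
    tab_rev <- transform(tab, ksv_Minv = rev(ksv_Minv))
    bwd <- classify_mechanism(tab_rev)$label
    expect_identical(bwd, switch(fwd, dynamic = "static",
                                 static = "dynamic", "indeterminate"))
  }
})

test_that("double-log and Stern-Volmer fits coincide on noiseless dynamic data", {
  ts <- simulate_titration(truth_params("dynamic", ksv_Minv = 5e4))
  sv <- stern_volmer_fit(ts)
  dl <- double_log_fit(ts)
  expect_equal(dl$kb_Minv, sv$ksv_Minv, tolerance = 1e-10)
  expect_equal(dl$n_sites, 1, tolerance = 1e-10)
})

test_that("double_log_fit drops unquenched points with a warning", {
  q <- c(0, 2, 4, 8, 16, 32) * 1e-6
  f <- c(1000, 1001, 950, 900, 820, 700)  # one point above F0
  ts <- titration_series(Q = q, F = f)
  expect_warning(fit <- double_log_fit(ts), "F >= F0")
  expect_equal(fit$n_points, 4L)

  mostly_bad <- titration_series(Q = q, F = c(1000, 1001, 1002, 1003, 1004,
                                              900))
  expect_warning(expect_error(double_log_fit(mostly_bad), "fewer than 3"))
})

test_that("classify_affinity brackets the reversible-transport range", {
  expect_identical(classify_affinity(1.60e4), "reversible_transport_range")
  expect_identical(classify_affinity(1e4), "reversible_transport_range")
  expect_identical(classify_affinity(15e4), "reversible_transport_range")
  expect_identical(classify_affinity(5e3), "below_reversible_range")
  expect_identical(classify_affinity(1e6), "above_reversible_range")
})

test_that("site_marker_analysis assigns the most-displaced marker's site", {
  markers <- data.frame(marker = c("ranitidine", "ibuprofen"),
                        kb_Minv = c(1.16e4, 0.91e4),
                        site = c("site I", "site II"))
  res <- site_marker_analysis(1.60e4, markers)
  expect_identical(res$assigned_site, "site II")
  expect_equal(res$table$reduction[res$table$marker == "ibuprofen"],
               1 - 0.91 / 1.60, tolerance = 1e-12)

  tie <- site_marker_analysis(1.60e4, transform(markers, kb_Minv = 1e4))
  expect_identical(tie$assigned_site, "indeterminate")

  single <- site_marker_analysis(
    1e4, data.frame(marker = "warfarin", kb_Minv = 5e3, site = "site I"))
  expect_identical(single$assigned_site, "site I")

  expect_error(site_marker_analysis(
    1e4, data.frame(marker = "x", kb_Minv = 0, site = "s")), "> 0")
})
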