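test_that("exact log-linear data is fitted perfectly and inverts", {
  conc <- design_concentrations(12, 10, 1300, "grid")
  em <- simulate_emf(conc, clean_emf_cfg(n_electrodes = 1))
  m <- fit_nikolsky(em, conc)
  e <- m$electrodes[["E1"]]
  expect_equal(e$e0, 400, tolerance = 1e-10)
  expect_equal(e$slope, -55, tolerance = 1e-10)
  expect_equal(e$fit_r2, 1, tolerance = 1e-12)

  # closed-form inversion: 290 mV -> 100 mg/L
  single <- electrode_set(matrix(290, 1, 1, dimnames = list("s1", "E1")))
  expect_equal(unname(as.numeric(predict_conc(m, single))), 100,
               tolerance = 1e-10)

  # zero-noise round trip over the whole series
  ph <- predict_conc(m, em)
  expect_equal(as.numeric(ph), as.numeric(conc), tolerance = 1e-8)
})

test_that("fit_r2 matches an independent 1 - SSE/SST computation", {
  conc <- design_concentrations(30, 10, 1300, "grid")
  em <- simulate_emf(conc, emf_sim_config(seed = 12))
  m <- fit_nikolsky(em, conc)
  lc <- log10(as.numeric(conc))
  for (id in colnames(em$emf)) {
    y <- em$emf[, id]
    co <- stats::coef(stats::lm(y ~ lc))
    sse <- sum((y - co[1] - co[2] * lc)^2)
    expect_equal(m$electrodes[[id]]$fit_r2,
                 1 - sse / sum((y - mean(y))^2), tolerance = 1e-12)
  }
})

test_that("degenerate calibration inputs are rejected", {
  em <- electrode_set(matrix(rnorm(9), 3, 3))
  expect_error(fit_nikolsky(em, conc_vector(rep(100, 3))), "distinct")
  expect_error(fit_nikolsky(em[1:2], conc_vector(c(10, 20))), ">= 3")
  expect_error(predict_conc(list(), em), "state error")
})

test_that("slope recovery is accurate under measurement noise", {
  conc <- design_concentrations(56, 10, 1300, "grid")
  hits <- 0L
  for (r in 1:20) {
    em <- simulate_emf(conc, emf_sim_config(n_electrodes = 1, e0 = 400,
                                            slope = -55, drift_rate = 0,
                                            noise_sd = 2, seed = 700 + r))
    sl <- fit_nikolsky(em, conc)$electrodes[["E1"]]$slope
    if (abs(sl + 55) < 3) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("geometric-mean aggregation combines electrodes on the log scale", {
  # craft a model whose three electrodes predict 50, 100, 200 for one sample
  conc <- design_concentrations(10, 10, 1300, "grid")
  em <- simulate_emf(conc, emf_sim_config(n_electrodes = 3, e0 = 400,
                                          slope = -55, drift_rate = 0,
                                          noise_sd = 0))
  m <- fit_nikolsky(em, conc)
  emf_vals <- vapply(c(50, 100, 200), function(cc) 400 - 55 * log10(cc),
                     numeric(1))
  one <- electrode_set(matrix(emf_vals, 1, 3,
                              dimnames = list("s1", c("E1", "E2", "E3"))))
  expect_equal(unname(as.numeric(suppressWarnings(predict_conc(m, one)))),
               (50 * 100 * 200)^(1 / 3), tolerance = 1e-10)
})

test_that("out-of-range predictions warn instead of clipping", {
  conc <- design_concentrations(10, 100, 500, "grid")
  em <- simulate_emf(conc, clean_emf_cfg(n_electrodes = 1))
  m <- fit_nikolsky(em, conc)
  hot <- electrode_set(matrix(400 - 55 * log10(5000), 1, 1,
                              dimnames = list("s1", "E1")))
  expect_warning(p <- predict_conc(m, hot), "outside the calibration range")
  expect_equal(unname(as.numeric(p)), 5000, tolerance = 1e-8)
})

test_that("two-point normalization removes offsets and reduces drift spread", {
  ref_lo <- c(conc = 10, emf = 400 - 55 * 1)
  ref_hi <- c(conc = 1000, emf = 400 - 55 * 3)
  conc <- design_concentrations(20, 10, 1000, "grid")
  em <- simulate_emf(conc, clean_emf_cfg(n_electrodes = 1))

  # already on the target line: unchanged
  same <- two_point_normalize(em, ref_lo, ref_hi,
                              measured_low = ref_lo[["emf"]],
                              measured_high = ref_hi[["emf"]])
  expect_equal(same$emf, em$emf, tolerance = 1e-10)

  # +10 mV constant offset: removed exactly
  off <- electrode_set(em$emf + 10)
  fixed <- two_point_normalize(off, ref_lo, ref_hi,
                               measured_low = ref_lo[["emf"]] + 10,
                               measured_high = ref_hi[["emf"]] + 10)
  expect_equal(fixed$emf, em$emf, tolerance = 1e-10)

  # drifted electrodes: spread across electrodes at fixed conc shrinks
  cfg <- emf_sim_config(e0 = c(400, 410, 390), slope = -55,
                        drift_rate = 0, noise_sd = 0)
  emd <- simulate_emf(conc, cfg)
  m_lo <- 400 - 55 * 1 + c(0, 10, -10)
  m_hi <- 400 - 55 * 3 + c(0, 10, -10)
  norm <- two_point_normalize(emd, ref_lo, ref_hi, m_lo, m_hi)
  spread_raw <- mean(apply(emd$emf, 1, function(r) diff(range(r))))
  spread_norm <- mean(apply(norm$emf, 1, function(r) diff(range(r))))
  expect_lt(spread_norm, spread_raw)

  expect_error(two_point_normalize(em, c(conc = 100, emf = 1),
                                   c(conc = 100, emf = 2), 1, 2), "distinct")
})
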