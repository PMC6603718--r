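test_that("concentration designs cover the requested range", {
  cv <- design_concentrations(80, 10, 1300, "grid")
  expect_length(cv, 80)
  expect_equal(min(cv), 10)
  expect_equal(max(cv), 1300)
  # log-spaced grid: ratios between consecutive levels are constant
  expect_equal(diff(log10(as.numeric(cv))), rep(diff(log10(c(10, 1300))) / 79, 79))

  u <- design_concentrations(50, 10, 1300, "uniform", seed = 4)
  expect_true(all(u >= 10 & u <= 1300))
  expect_identical(as.numeric(u),
                   as.numeric(design_concentrations(50, 10, 1300, "uniform",
                                                    seed = 4)))
})

test_that("degenerate design arguments are rejected", {
  expect_error(design_concentrations(2, 1, 1), "lo < hi")
  expect_error(design_concentrations(1, 10, 1300), "n must be")
  expect_error(design_concentrations(10, -5, 10), "lo < hi")
})

test_that("log-uniform sampling centres on the geometric mean of the bounds", {
  x <- design_concentrations(1e4, 10, 1300, "log_uniform", seed = 11)
  gm <- sqrt(10 * 1300)
  expect_gt(stats::median(x), gm * 0.9)
  expect_lt(stats::median(x), gm * 1.1)
})

test_that("noise-free spectra follow the Beer-Lambert model exactly", {
  conc <- conc_vector(c(50, 200, 800))
  # no analyte signal: all spectra equal i0 * 10^-baseline
  cfg0 <- clean_spectra_cfg(band_gains = c(0, 0))
  sp0 <- simulate_spectra(conc, cfg0)
  expected <- cfg0$i0 * 10^(-cfg0$baseline_absorbance)
  for (i in 1:3) expect_equal(unname(sp0$intensity[i, ]), expected)

  # monotone: higher concentration absorbs more at the band centre
  cfg <- clean_spectra_cfg()
  sp <- simulate_spectra(conc, cfg)
  j <- which.min(abs(cfg$wavelength_grid - 945))
  expect_true(all(diff(sp$intensity[, j]) < 0))

  # analytic inversion at a band centre recovers gain * conc
  j2 <- which.min(abs(cfg$wavelength_grid - cfg$band_centers[1]))
  a_meas <- -log10(sp$intensity[, j2] / cfg$i0) -
    cfg$baseline_absorbance[j2]
  shape <- vapply(seq_along(cfg$band_centers), function(b) {
    exp(-(cfg$wavelength_grid[j2] - cfg$band_centers[b])^2 /
          (2 * cfg$band_widths[b]^2))
  }, numeric(1))
  a_model <- as.numeric(conc) * sum(cfg$band_gains * shape)
  expect_equal(unname(a_meas), a_model, tolerance = 1e-10)
})

test_that("spectral simulator validates its configuration", {
  expect_error(spectra_sim_config(band_centers = c(945, 2500)),
               "inside the wavelength grid")
  expect_error(spectra_sim_config(noise_sd = -1), ">= 0")
  expect_error(spectra_sim_config(i0 = 0), "i0")
})

test_that("noise-free EMF is the closed-form Nikolsky response", {
  conc <- conc_vector(c(100, 100, 100))
  em <- simulate_emf(conc, clean_emf_cfg(n_electrodes = 1))
  expect_equal(unname(em$emf[, 1]), rep(400 - 55 * 2, 3))

  # exact log-linear data: OLS recovers the slope exactly
  conc2 <- design_concentrations(20, 10, 1300, "grid")
  em2 <- simulate_emf(conc2, clean_emf_cfg(n_electrodes = 1))
  fit <- stats::lm.fit(cbind(1, log10(as.numeric(conc2))), em2$emf[, 1])
  expect_equal(unname(fit$coefficients), c(400, -55), tolerance = 1e-12)
})

test_that("EMF simulation is reproducible and drift/interference behave", {
  conc <- design_concentrations(30, 10, 1300, "grid")
  a <- simulate_emf(conc, emf_sim_config(seed = 7))
  b <- simulate_emf(conc, emf_sim_config(seed = 7))
  expect_identical(a$emf, b$emf)

  # pure drift moves later samples by drift_rate * index
  cfgd <- emf_sim_config(n_electrodes = 1, e0 = 400, slope = -55,
                         drift_rate = -0.5, noise_sd = 0)
  cc <- conc_vector(rep(100, 5))
  emd <- simulate_emf(cc, cfgd)
  expect_equal(unname(emd$emf[, 1]), 290 - 0.5 * (0:4))

  # a selectivity coefficient shifts the effective activity
  cfgk <- emf_sim_config(n_electrodes = 1, e0 = 400, slope = -55,
                         drift_rate = 0, noise_sd = 0, k_sel = 0.5)
  emk <- simulate_emf(conc_vector(100), cfgk, interferent = 100)
  expect_equal(unname(emk$emf[1, 1]), 400 - 55 * log10(150))

  expect_error(emf_sim_config(slope = 55), "negative")
})

test_that("more noise never improves expected electrode calibration error", {
  conc <- design_concentrations(56, 10, 1300, "grid")
  mean_rmse <- vapply(c(0, 4, 16), function(nz) {
    errs <- vapply(1:30, function(r) {
      em <- simulate_emf(conc, emf_sim_config(n_electrodes = 1, e0 = 400,
                                              slope = -55, drift_rate = 0,
                                              noise_sd = nz,
                                              seed = 100 + r))
      m <- fit_nikolsky(em, conc)
      ph <- suppressWarnings(predict_conc(m, em))
      score_metrics(as.numeric(conc), as.numeric(ph))$rmse
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_rmse) >= 0))
})
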