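# Shared fixture builders. Everything is generated in code at test time.

# Noise-free simulator configurations (analytically invertible).
clean_spectra_cfg <- function(...) {
  spectra_sim_config(scatter_mult_sd = 0, scatter_add_sd = 0, noise_sd = 0, ...)
}

clean_emf_cfg <- function(...) {
  emf_sim_config(e0 = 400, slope = -55, drift_rate = 0, noise_sd = 0, ...)
}

# Study-condition regimes for the end-to-end checks. "low" is near the
# noise floor; "mid" matches the sensor quality the original study reports
# (per-electrode test R2 ~0.6, NIR channel well below its calibration fit).
study_regime <- function(level = c("low", "mid")) {
  level <- match.arg(level)
  if (level == "low") {
    list(spectra = list(noise_sd = 5e-4, scatter_mult_sd = 0.002,
                        scatter_add_sd = 5e-4),
         emf = list(noise_sd = 0.5))
  } else {
    list(spectra = list(noise_sd = 0.1, scatter_mult_sd = 0.5,
                        scatter_add_sd = 0.2),
         emf = list(noise_sd = 12))
  }
}

# 80-sample study set with a rank-stratified 56/24 split.
make_study_data <- function(seed, level = "mid") {
  rg <- study_regime(level)
  conc <- design_concentrations(80, 10, 1300, "grid")
  sp <- simulate_spectra(conc, do.call(spectra_sim_config,
                                       c(rg$spectra, list(seed = seed))))
  em <- simulate_emf(conc, do.call(emf_sim_config,
                                   c(rg$emf, list(seed = seed + 500L))))
  split <- split_samples(names(conc), 56, 24, "rank_stratified",
                         seed = seed + 900L, conc = conc)
  ical <- names(conc) %in% split$calib
  itst <- names(conc) %in% split$test
  list(conc = conc, spectra = sp, emf = em, split = split,
       calib = list(spectra = sp[ical], emf = em[ical], y = conc[ical]),
       test = list(spectra = sp[itst], emf = em[itst], y = conc[itst]))
}

# Exactly rank-3 predictor matrix with a response living on the 3 factors.
make_planted <- function(n, p, seed, noise_sd = 0) {
  withr::with_seed(seed, {
    Tm <- matrix(stats::rnorm(n * 3), n, 3)
    L <- matrix(stats::rnorm(p * 3), p, 3)
    x <- Tm %*% t(L)
    y <- drop(Tm %*% c(2, -1, 0.5)) + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = y)
  })
}

rand_spectra <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    spectra_set(matrix(stats::rnorm(n * p, 10), n, p), seq_len(p) * 5 + 900)
  })
}
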