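#' Design a concentration series
#'
#' Lay out phosphate concentrations over a working range, mirroring a bench
#' dilution series. The default range (10-1300 mg/L) spans the variation a
#' hydroponic paprika solution can plausibly reach, including pump faults.
#'
#' @param n number of samples (>= 2).
#' @param lo,hi range bounds, mg/L, both > 0 and `lo < hi`.
#' @param scheme `"grid"` (levels evenly spaced in log-concentration,
#'   endpoints included), `"uniform"` (random uniform on the linear scale) or
#'   `"log_uniform"` (random uniform in log10 space).
#' @param seed integer seed for the random schemes; the grid scheme is
#'   deterministic regardless.
#' @return a [conc_vector].
#' @examples
#' design_concentrations(80, 10, 1300, "grid")
#' @export
design_concentrations <- function(n, lo = 10, hi = 1300,
                                  scheme = c("grid", "uniform", "log_uniform"),
                                  seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi <= lo) {
    stop("need 0 < lo < hi (mg/L)", call. = FALSE)
  }
  conc <- switch(scheme,
    grid = 10^seq(log10(lo), log10(hi), length.out = n),
    uniform = with_seed_opt(seed, stats::runif(n, lo, hi)),
    log_uniform = with_seed_opt(seed, 10^stats::runif(n, log10(lo), log10(hi)))
  )
  conc_vector(conc)
}

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Spectral simulator configuration
#'
#' Parameters of the Beer-Lambert style transmission model used by
#' [simulate_spectra()]. Absorbance at wavelength w for concentration c is
#' `baseline(w) + sum_b gain_b * c * exp(-(w - center_b)^2 / (2 width_b^2))`,
#' transmittance is `10^(-A)`, and the recorded intensity is
#' `m * i0 * T + add + noise` with a per-spectrum multiplicative scatter
#' factor `m ~ N(1, scatter_mult_sd)` and additive offset
#' `add ~ N(0, scatter_add_sd)`.
#'
#' Defaults place two Gaussian phosphate bands at 945 and 1070 nm (widths 15
#' and 30 nm), inside the 930-960 and 1020-1120 nm absorption windows
#' reported for PO4 in the NIR, on a 128-point 904-1700 nm grid typical of a
#' compact InGaAs spectrometer.
#'
#' @param wavelength_grid ascending wavelengths, nm.
#' @param band_centers,band_widths,band_gains per-band Gaussian centre (nm),
#'   sigma (nm) and absorbance gain per (mg/L).
#' @param baseline_absorbance per-wavelength baseline absorbance; a single
#'   function of wavelength or a vector matching the grid.
#' @param scatter_mult_sd,scatter_add_sd per-spectrum scatter parameters.
#' @param noise_sd per-point intensity noise sd.
#' @param i0 source intensity (arbitrary detector units).
#' @param seed integer seed.
#' @return a `spectra_sim_config` list.
#' @export
spectra_sim_config <- function(wavelength_grid = seq(904, 1700, length.out = 128),
                               band_centers = c(945, 1070),
                               band_widths = c(15, 30),
                               band_gains = c(2.5e-4, 3.5e-4),
                               baseline_absorbance = NULL,
                               scatter_mult_sd = 0.02,
                               scatter_add_sd = 0.005,
                               noise_sd = 0.003,
                               i0 = 1,
                               seed = 1L) {
  wavelength_grid <- as.numeric(wavelength_grid)
  if (any(diff(wavelength_grid) <= 0)) {
    stop("wavelength_grid must be strictly ascending", call. = FALSE)
  }
  nb <- length(band_centers)
  if (length(band_widths) != nb || length(band_gains) != nb) {
    stop("band_centers, band_widths, band_gains must share a length",
         call. = FALSE)
  }
  if (any(band_centers < min(wavelength_grid) |
          band_centers > max(wavelength_grid))) {
    stop("band centers must lie inside the wavelength grid", call. = FALSE)
  }
  if (any(band_widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (scatter_mult_sd < 0 || scatter_add_sd < 0 || noise_sd < 0) {
    stop("scatter/noise sds must be >= 0", call. = FALSE)
  }
  if (i0 <= 0) stop("i0 must be > 0", call. = FALSE)
  if (is.null(baseline_absorbance)) {
    # gentle ramp: water/OH overtone background rising toward 1700 nm
    baseline_absorbance <- 0.35 + 0.25 * (wavelength_grid - min(wavelength_grid)) /
      diff(range(wavelength_grid))
  } else if (is.function(baseline_absorbance)) {
    baseline_absorbance <- baseline_absorbance(wavelength_grid)
  }
  if (length(baseline_absorbance) != length(wavelength_grid) ||
      any(!is.finite(baseline_absorbance))) {
    stop("baseline_absorbance must be finite and match the grid", call. = FALSE)
  }
  structure(list(wavelength_grid = wavelength_grid,
                 band_centers = band_centers, band_widths = band_widths,
                 band_gains = band_gains,
                 baseline_absorbance = as.numeric(baseline_absorbance),
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd,
                 noise_sd = noise_sd, i0 = i0, seed = as.integer(seed)),
            class = "spectra_sim_config")
}

#' Simulate transmission NIR spectra
#'
#' Generates one transmission spectrum per sample under the Beer-Lambert
#' model described in [spectra_sim_config()]. With all noise and scatter
#' standard deviations set to zero the map from concentration to spectrum is
#' deterministic and analytically invertible at any band centre.
#'
#' @param conc a [conc_vector].
#' @param cfg a [spectra_sim_config()].
#' @return a [spectra_set] of recorded intensities.
#' @export
simulate_spectra <- function(conc, cfg = spectra_sim_config()) {
  stopifnot(inherits(conc, "conc_vector"), inherits(cfg, "spectra_sim_config"))
  wl <- cfg$wavelength_grid
  n <- length(conc); p <- length(wl)
  # band shape matrix: p x n_bands
  shape <- vapply(seq_along(cfg$band_centers), function(b) {
    exp(-(wl - cfg$band_centers[b])^2 / (2 * cfg$band_widths[b]^2))
  }, numeric(p))
  # absorbance: n x p
  absorb <- matrix(0, n, p)
  for (b in seq_along(cfg$band_centers)) {
    absorb <- absorb + cfg$band_gains[b] * outer(as.numeric(conc), shape[, b])
  }
  absorb <- sweep(absorb, 2L, cfg$baseline_absorbance, "+")
  trans <- 10^(-absorb)
  intensity <- with_seed_opt(cfg$seed, {
    m <- 1 + stats::rnorm(n, 0, cfg$scatter_mult_sd)
    add <- stats::rnorm(n, 0, cfg$scatter_add_sd)
    eps <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
    (m * cfg$i0) * trans + add + eps
  })
  spectra_set(intensity, wl, sample_ids = names(conc))
}

#' EMF simulator configuration
#'
#' Parameters of the near-Nernstian cobalt-electrode model used by
#' [simulate_emf()]. Each electrode k responds as
#' `EMF = e0_k + slope_k * log10(c + k_sel_k * c_interferent) + drift_rate_k * t + noise`
#' with `t` the 0-based sample index (a proxy for slow conditioning drift over
#' a measurement session). Slopes are negative: phosphate is an anion, so EMF
#' falls with activity. Selectivity coefficients default to zero (log-linear
#' primary-ion response only).
#'
#' @param n_electrodes number of cobalt electrodes.
#' @param e0 per-electrode intercept, mV (recycled to `n_electrodes`).
#' @param slope per-electrode response, mV per decade; all < 0.
#' @param drift_rate per-electrode drift, mV per sample index.
#' @param noise_sd EMF noise sd, mV.
#' @param k_sel per-electrode selectivity coefficient for an optional
#'   interfering ion (0 disables the term).
#' @param seed integer seed.
#' @return an `emf_sim_config` list.
#' @export
emf_sim_config <- function(n_electrodes = 3,
                           e0 = c(400, 392, 408),
                           slope = c(-55, -52, -58),
                           drift_rate = c(-0.05, -0.08, -0.03),
                           noise_sd = 2,
                           k_sel = 0,
                           seed = 1L) {
  n_electrodes <- as.integer(n_electrodes)
  if (n_electrodes < 1L) stop("need >= 1 electrode", call. = FALSE)
  e0 <- rep_len(as.numeric(e0), n_electrodes)
  slope <- rep_len(as.numeric(slope), n_electrodes)
  drift_rate <- rep_len(as.numeric(drift_rate), n_electrodes)
  k_sel <- rep_len(as.numeric(k_sel), n_electrodes)
  if (any(slope >= 0)) stop("electrode slopes must be negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(k_sel < 0)) stop("selectivity coefficients must be >= 0", call. = FALSE)
  structure(list(n_electrodes = n_electrodes, e0 = e0, slope = slope,
                 drift_rate = drift_rate, noise_sd = noise_sd,
                 k_sel = k_sel, seed = as.integer(seed)),
            class = "emf_sim_config")
}

#' Simulate multi-electrode EMF readings
#'
#' @param conc a [conc_vector].
#' @param cfg an [emf_sim_config()].
#' @param interferent optional per-sample interfering-ion concentration
#'   (mg/L) entering through the selectivity coefficients; default none.
#' @return an [electrode_set] (mV).
#' @export
simulate_emf <- function(conc, cfg = emf_sim_config(), interferent = NULL) {
  stopifnot(inherits(conc, "conc_vector"), inherits(cfg, "emf_sim_config"))
  n <- length(conc); k <- cfg$n_electrodes
  if (is.null(interferent)) interferent <- rep(0, n)
  if (length(interferent) != n || any(interferent < 0)) {
    stop("interferent must be a non-negative per-sample vector", call. = FALSE)
  }
  idx <- seq_len(n) - 1  # 0-based session time proxy
  emf <- matrix(0, n, k)
  for (j in seq_len(k)) {
    eff <- as.numeric(conc) + cfg$k_sel[j] * interferent
    emf[, j] <- cfg$e0[j] + cfg$slope[j] * log10(eff) + cfg$drift_rate[j] * idx
  }
  emf <- emf + with_seed_opt(cfg$seed,
                             matrix(stats::rnorm(n * k, 0, cfg$noise_sd), n, k))
  electrode_set(emf, electrode_ids = paste0("E", seq_len(k)),
                sample_ids = names(conc))
}
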