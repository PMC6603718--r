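#' Fit log-linear (Nikolsky-Eisenman form) electrode calibrations
#'
#' For each electrode, ordinary least squares of EMF (mV) on
#' `log10(concentration)`. This is the primary-ion form of the
#' Nikolsky-Eisenman response: a cobalt electrode in phosphate solution shows
#' a negative near-Nernstian slope per decade of concentration.
#' Concentration, not activity, is the regressor, matching routine nutrient
#' monitoring practice where activity coefficients are not resolved.
#'
#' @param emf an [electrode_set] of calibration readings.
#' @param conc the matching [conc_vector] (same samples, same order).
#' @return a `nikolsky_model`: per-electrode intercept `e0` (mV), `slope`
#'   (mV/decade) and calibration-line `fit_r2`.
#' @export
fit_nikolsky <- function(emf, conc) {
  stopifnot(inherits(emf, "electrode_set"), inherits(conc, "conc_vector"))
  check_aligned(emf, conc, "emf and conc")
  n <- length(conc)
  if (n < 3L) stop("need >= 3 calibration samples", call. = FALSE)
  lc <- log10(as.numeric(conc))
  if (length(unique(as.numeric(conc))) < 2L) {
    stop("rank error: need >= 2 distinct concentrations", call. = FALSE)
  }
  ids <- colnames(emf$emf)
  fits <- lapply(seq_along(ids), function(j) {
    y <- emf$emf[, j]
    fit <- stats::lm.fit(cbind(1, lc), y)
    e0 <- fit$coefficients[1]; slope <- fit$coefficients[2]
    sse <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    list(e0 = unname(e0), slope = unname(slope), fit_r2 = r2)
  })
  names(fits) <- ids
  structure(list(electrodes = fits,
                 conc_range = range(as.numeric(conc)),
                 n_calibration = n),
            class = "nikolsky_model")
}

#' @export
print.nikolsky_model <- function(x, ...) {
  cat(sprintf("<nikolsky_model> %d electrode(s), calibrated on %d samples\n",
              length(x$electrodes), x$n_calibration))
  for (id in names(x$electrodes)) {
    e <- x$electrodes[[id]]
    cat(sprintf("  %s: e0 = %.2f mV, slope = %.2f mV/decade, R2 = %.4f\n",
                id, e$e0, e$slope, e$fit_r2))
  }
  invisible(x)
}

#' Predict concentration from electrode EMF
#'
#' Inverts each electrode's calibration line,
#' `c_hat = 10^((EMF - e0) / slope)`. With `aggregate = "mean"` the
#' per-electrode predictions are combined by geometric mean (the arithmetic
#' mean on the log-concentration scale on which the model is linear).
#' Predictions outside the calibration range are returned as-is with a
#' warning, never clipped.
#'
#' @param model a fitted [fit_nikolsky()] model.
#' @param emf an [electrode_set] whose electrode ids match the model.
#' @param aggregate `"mean"` (geometric mean across electrodes, the default)
#'   or `"per_electrode"` (a matrix of per-electrode predictions).
#' @return a [conc_vector] (`"mean"`) or a sample x electrode matrix of
#'   predicted concentrations (`"per_electrode"`).
#' @export
predict_conc <- function(model, emf, aggregate = c("mean", "per_electrode")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(model, "nikolsky_model")) {
    stop("state error: model is not a fitted nikolsky_model", call. = FALSE)
  }
  stopifnot(inherits(emf, "electrode_set"))
  ids <- colnames(emf$emf)
  if (!all(ids %in% names(model$electrodes))) {
    stop("electrode ids do not match the fitted model", call. = FALSE)
  }
  pred <- vapply(ids, function(id) {
    e <- model$electrodes[[id]]
    10^((emf$emf[, id] - e$e0) / e$slope)
  }, numeric(nrow(emf$emf)))
  pred <- matrix(pred, nrow = nrow(emf$emf),
                 dimnames = list(sample_ids(emf), ids))
  out_of_range <- pred < model$conc_range[1] * (1 - 1e-10) |
    pred > model$conc_range[2] * (1 + 1e-10)
  if (any(out_of_range)) {
    warning(sprintf("%d prediction(s) fall outside the calibration range %.4g-%.4g mg/L",
                    sum(out_of_range), model$conc_range[1], model$conc_range[2]),
            call. = FALSE)
  }
  if (aggregate == "per_electrode") return(pred)
  conc_vector(exp(rowMeans(log(pred))), sample_ids(emf))
}

#' Two-point normalization of electrode responses
#'
#' Affine drift compensation using two standards of known concentration.
#' Each electrode's measured EMFs at the low and high standards are mapped
#' exactly onto a shared target line defined by the reference
#' (concentration, EMF) pairs; the same affine map is then applied to all of
#' that electrode's readings. Offered as optional session-to-session drift
#' compensation; calibration on raw readings remains the default workflow.
#'
#' @param emf an [electrode_set] to normalize.
#' @param ref_low,ref_high target points, each `c(conc = <mg/L>, emf = <mV>)`
#'   with distinct positive concentrations.
#' @param measured_low,measured_high per-electrode measured EMF (mV) at the
#'   low/high standard, length = number of electrodes.
#' @return the normalized [electrode_set].
#' @export
two_point_normalize <- function(emf, ref_low, ref_high,
                                measured_low, measured_high) {
  stopifnot(inherits(emf, "electrode_set"))
  c_lo <- ref_low[["conc"]]; c_hi <- ref_high[["conc"]]
  if (!is.finite(c_lo) || !is.finite(c_hi) || c_lo <= 0 || c_hi <= 0 ||
      c_lo == c_hi) {
    stop("reference concentrations must be distinct and positive",
         call. = FALSE)
  }
  k <- ncol(emf$emf)
  measured_low <- rep_len(as.numeric(measured_low), k)
  measured_high <- rep_len(as.numeric(measured_high), k)
  t_lo <- ref_low[["emf"]]; t_hi <- ref_high[["emf"]]
  out <- emf$emf
  for (j in seq_len(k)) {
    span <- measured_high[j] - measured_low[j]
    if (abs(span) < 1e-12) {
      stop("electrode shows no span between the two standards", call. = FALSE)
    }
    gain <- (t_hi - t_lo) / span
    out[, j] <- t_lo + gain * (emf$emf[, j] - measured_low[j])
  }
  electrode_set(out)
}
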