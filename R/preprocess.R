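#' Moving-average smoothing
#'
#' Centred moving average along the wavelength axis. At the spectrum edges
#' the window shrinks to the points actually available, so the output keeps
#' the input length and no values are fabricated beyond the recorded range.
#'
#' @param s a [spectra_set].
#' @param window odd window width in points, `1 <= window <= n_wavelengths`.
#' @return a smoothed [spectra_set].
#' @export
moving_average <- function(s, window) {
  stopifnot(inherits(s, "spectra_set"))
  p <- ncol(s$intensity)
  if (!is.numeric(window) || length(window) != 1L || window %% 2 != 1 ||
      window < 1 || window > p) {
    stop("window must be an odd integer in [1, n_wavelengths]", call. = FALSE)
  }
  if (window == 1) return(s)
  half <- (window - 1) / 2
  lo <- pmax(seq_len(p) - half, 1L)
  hi <- pmin(seq_len(p) + half, p)
  sm <- s$intensity
  for (j in seq_len(p)) {
    sm[, j] <- rowMeans(s$intensity[, lo[j]:hi[j], drop = FALSE])
  }
  spectra_set(sm, s$wavelengths, sample_ids(s))
}

#' Standard normal variate
#'
#' Per-spectrum centring and unit-variance scaling (`n - 1` denominator), the
#' classical scatter correction that removes per-spectrum offset and gain.
#'
#' @param s a [spectra_set]; every spectrum must have positive variance.
#' @return the SNV-transformed [spectra_set].
#' @export
snv <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  m <- rowMeans(s$intensity)
  sd_ <- apply(s$intensity, 1L, stats::sd)
  bad <- which(sd_ <= 0 | !is.finite(sd_))
  if (length(bad)) {
    stop(sprintf("snv: zero-variance spectrum for sample(s): %s",
                 paste(sample_ids(s)[bad], collapse = ", ")), call. = FALSE)
  }
  out <- (s$intensity - m) / sd_
  spectra_set(out, s$wavelengths, sample_ids(s))
}

#' Multiplicative scatter correction
#'
#' `fit_msc()` stores the reference spectrum (the column mean of a fitting
#' set, normally the calibration set). `apply_msc()` regresses each spectrum
#' on the reference, `x ~ a + b * ref`, and returns `(x - a) / b`. The
#' reference is fit once and reused for new spectra, so test data never leak
#' into the correction.
#'
#' @param s a [spectra_set] (the fitting set for `fit_msc`).
#' @return `fit_msc`: an `msc_reference`; `apply_msc`: a corrected
#'   [spectra_set].
#' @export
fit_msc <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (nrow(s$intensity) < 1L) stop("fit_msc: empty fitting set", call. = FALSE)
  structure(list(reference = colMeans(s$intensity),
                 wavelengths = s$wavelengths),
            class = "msc_reference")
}

#' @rdname fit_msc
#' @param ref an `msc_reference` from [fit_msc()].
#' @export
apply_msc <- function(s, ref) {
  stopifnot(inherits(s, "spectra_set"), inherits(ref, "msc_reference"))
  if (length(ref$reference) != ncol(s$intensity)) {
    stop("apply_msc: reference length does not match spectra", call. = FALSE)
  }
  r <- ref$reference
  rc <- r - mean(r)
  denom <- sum(rc^2)
  out <- t(apply(s$intensity, 1L, function(x) {
    b <- sum((x - mean(x)) * rc) / denom
    if (abs(b) < 1e-12) {
      stop("apply_msc: degenerate spectrum (slope on reference ~ 0)",
           call. = FALSE)
    }
    a <- mean(x) - b * mean(r)
    (x - a) / b
  }))
  spectra_set(out, s$wavelengths, sample_ids(s))
}

#' Pretreatment pipelines
#'
#' A pipeline is written as a compact spec string: `"raw"`, `"ma:11"`,
#' `"ma:11+snv"`, `"ma:11+msc"`, mirroring the four pretreatments compared in
#' the calibration study (raw, 11-point moving average, moving average + SNV,
#' moving average + MSC). `fit_pretreatment()` fits any data-dependent step
#' (the MSC reference) on the supplied calibration spectra;
#' `predict(<pretreatment>, s)` replays the frozen pipeline on new spectra.
#'
#' @param s calibration [spectra_set].
#' @param spec pipeline spec string.
#' @return a `pretreatment` object.
#' @export
fit_pretreatment <- function(s, spec = "raw") {
  steps <- parse_pretreatment(spec)
  cur <- s
  fitted <- list()
  for (st in steps) {
    if (st$op == "msc") {
      st$ref <- fit_msc(cur)
    }
    cur <- apply_step(cur, st)
    fitted[[length(fitted) + 1L]] <- st
  }
  structure(list(spec = spec, steps = fitted), class = "pretreatment")
}

#' @rdname fit_pretreatment
#' @param object a fitted `pretreatment`.
#' @param ... unused.
#' @export
predict.pretreatment <- function(object, s, ...) {
  cur <- s
  for (st in object$steps) cur <- apply_step(cur, st)
  cur
}

apply_step <- function(s, st) {
  switch(st$op,
    raw = s,
    ma = moving_average(s, st$window),
    snv = snv(s),
    msc = apply_msc(s, st$ref),
    stop("unknown pretreatment step: ", st$op, call. = FALSE))
}

parse_pretreatment <- function(spec) {
  parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty pretreatment spec", call. = FALSE)
  lapply(parts, function(tok) {
    tok <- trimws(tok)
    if (tok == "raw") return(list(op = "raw"))
    if (tok == "snv") return(list(op = "snv"))
    if (tok == "msc") return(list(op = "msc"))
    if (grepl("^ma:[0-9]+$", tok)) {
      return(list(op = "ma", window = as.integer(sub("^ma:", "", tok))))
    }
    stop("cannot parse pretreatment token: ", tok, call. = FALSE)
  })
}

#' Convert intensity to absorbance
#'
#' `-log10(I / i0)` applied pointwise; used when regression on absorbance
#' rather than raw intensity is wanted.
#'
#' @param s a [spectra_set] of intensities (all > 0).
#' @param i0 source intensity.
#' @return an absorbance [spectra_set].
#' @export
to_absorbance <- function(s, i0 = 1) {
  stopifnot(inherits(s, "spectra_set"))
  if (any(s$intensity <= 0)) {
    stop("to_absorbance: intensities must be > 0", call. = FALSE)
  }
  spectra_set(-log10(s$intensity / i0), s$wavelengths, sample_ids(s))
}
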