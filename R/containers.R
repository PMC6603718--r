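#' Concentration vector
#'
#' A named numeric vector of phosphate concentrations (mg/L), one entry per
#' sample. Names are the sample identifiers. All values must be finite and
#' strictly positive (the electrode channel works on `log10(conc)`).
#'
#' @param conc numeric vector of concentrations, mg/L.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `"S001"`, `"S002"`, ...
#' @return a `conc_vector`: named numeric vector with class attribute.
#' @export
conc_vector <- function(conc, sample_ids = NULL) {
  conc <- as.numeric(conc)
  if (length(conc) < 1L) {
    stop("conc_vector: need at least one sample", call. = FALSE)
  }
  if (any(!is.finite(conc))) {
    stop("conc_vector: concentrations must be finite", call. = FALSE)
  }
  if (any(conc <= 0)) {
    stop("conc_vector: concentrations must be > 0 mg/L", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%03d", seq_along(conc))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(conc)) {
    stop("conc_vector: sample_ids length must match conc", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("conc_vector: duplicated sample ids", call. = FALSE)
  }
  names(conc) <- sample_ids
  structure(conc, class = "conc_vector")
}

#' @export
print.conc_vector <- function(x, ...) {
  cat(sprintf("<conc_vector> %d samples, %.4g-%.4g mg/L\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' @export
as.data.frame.conc_vector <- function(x, ...) {
  data.frame(sample_id = names(x), po4_mg_per_l = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' @export
`[.conc_vector` <- function(x, i, ...) {
  y <- unclass(x)[i]
  structure(y, class = "conc_vector")
}

#' Spectra container
#'
#' Sample-by-wavelength intensity matrix with a strictly ascending wavelength
#' axis in nanometres. Row names are sample identifiers. Values may be raw
#' detector intensities or any pretreated quantity.
#'
#' @param intensity numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector (nm), strictly ascending, one per column.
#' @param sample_ids character vector of row identifiers; defaults to
#'   existing row names or `"S001"`, ...
#' @return a `spectra_set` object (list with `intensity`, `wavelengths`).
#' @export
spectra_set <- function(intensity, wavelengths, sample_ids = NULL) {
  intensity <- as.matrix(intensity)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(intensity) != length(wavelengths)) {
    stop("spectra_set: wavelength count must equal column count", call. = FALSE)
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("spectra_set: wavelengths must be strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("spectra_set: intensity must be finite (no NaN/Inf)", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(intensity)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(intensity)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensity)) {
    stop("spectra_set: sample_ids length must match row count", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("spectra_set: duplicated sample ids", call. = FALSE)
  }
  rownames(intensity) <- sample_ids
  colnames(intensity) <- format_wl(wavelengths)
  structure(list(intensity = intensity, wavelengths = wavelengths),
            class = "spectra_set")
}

format_wl <- function(wl) formatC(wl, format = "g", digits = 15)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.6g-%.6g nm)\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$intensity[i, , drop = FALSE], x$wavelengths)
}

#' @rdname spectra_set
#' @param x a `spectra_set`.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.spectra_set <- function(x) rownames(x$intensity)

#' @export
sample_ids.electrode_set <- function(x) rownames(x$emf)

#' @export
sample_ids.conc_vector <- function(x) names(x)

#' Electrode EMF container
#'
#' Sample-by-electrode matrix of electromotive force readings (mV) against a
#' common reference electrode.
#'
#' @param emf numeric matrix, samples in rows, electrodes in columns.
#' @param electrode_ids column identifiers; defaults to `"E1"`, `"E2"`, ...
#' @param sample_ids row identifiers.
#' @return an `electrode_set` object.
#' @export
electrode_set <- function(emf, electrode_ids = NULL, sample_ids = NULL) {
  emf <- as.matrix(emf)
  if (ncol(emf) < 1L) stop("electrode_set: need >= 1 electrode", call. = FALSE)
  if (any(!is.finite(emf))) {
    stop("electrode_set: EMF values must be finite", call. = FALSE)
  }
  if (is.null(electrode_ids)) {
    electrode_ids <- colnames(emf)
    if (is.null(electrode_ids)) electrode_ids <- paste0("E", seq_len(ncol(emf)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(emf)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(emf)))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("electrode_set: duplicated sample ids", call. = FALSE)
  }
  if (length(sample_ids) != nrow(emf) || length(electrode_ids) != ncol(emf)) {
    stop("electrode_set: id lengths must match matrix dimensions", call. = FALSE)
  }
  dimnames(emf) <- list(sample_ids, as.character(electrode_ids))
  structure(list(emf = emf), class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set> %d samples x %d electrodes (%s)\n",
              nrow(x$emf), ncol(x$emf),
              paste(colnames(x$emf), collapse = ", ")))
  invisible(x)
}

#' @export
`[.electrode_set` <- function(x, i, ...) {
  electrode_set(x$emf[i, , drop = FALSE])
}

# Check that two containers carry the same samples in the same order.
check_aligned <- function(a, b, what = "inputs") {
  ia <- sample_ids(a); ib <- sample_ids(b)
  if (length(ia) != length(ib) || !all(ia == ib)) {
    stop(sprintf("sample ids of %s do not match (alignment error)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
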