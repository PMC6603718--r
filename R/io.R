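#' Read and write the three sensor CSV formats
#'
#' All tables are plain comma-separated UTF-8 with a header row:
#' * spectra: first column `sample_id`, remaining columns named by
#'   wavelength in nm (ascending);
#' * EMF: first column `sample_id`, remaining columns named by electrode id;
#' * concentration: columns `sample_id`, `po4_mg_per_l`.
#'
#' Readers validate numeric cells, unique sample ids and (for spectra) an
#' ascending wavelength header, and report the offending row or column.
#'
#' @param path CSV file path.
#' @return the corresponding container ([spectra_set], [electrode_set],
#'   [conc_vector]).
#' @export
read_spectra_csv <- function(path) {
  df <- read_checked(path, min_cols = 2L)
  wl <- suppressWarnings(as.numeric(sub("^X", "", names(df)[-1L])))
  if (any(is.na(wl))) {
    stop("spectra header must be numeric wavelengths (nm)", call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelength header must be strictly ascending", call. = FALSE)
  }
  spectra_set(numeric_block(df, path), wl, df[[1L]])
}

#' @rdname read_spectra_csv
#' @export
read_emf_csv <- function(path) {
  df <- read_checked(path, min_cols = 2L)
  electrode_set(numeric_block(df, path),
                electrode_ids = names(df)[-1L], sample_ids = df[[1L]])
}

#' @rdname read_spectra_csv
#' @export
read_conc_csv <- function(path) {
  df <- read_checked(path, min_cols = 2L)
  if (!all(c("sample_id", "po4_mg_per_l") %in% names(df))) {
    stop("concentration CSV needs columns sample_id, po4_mg_per_l",
         call. = FALSE)
  }
  conc_vector(check_numeric_col(df$po4_mg_per_l, "po4_mg_per_l", path),
              df$sample_id)
}

read_checked <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  if (ncol(df) < min_cols) {
    stop(sprintf("%s: expected >= %d columns", path, min_cols), call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("%s: duplicated sample id '%s'", path, dup[1L]), call. = FALSE)
  }
  df
}

numeric_block <- function(df, path) {
  m <- vapply(names(df)[-1L], function(cn) {
    check_numeric_col(df[[cn]], cn, path)
  }, numeric(nrow(df)))
  matrix(m, nrow = nrow(df), dimnames = list(df[[1L]], names(df)[-1L]))
}

check_numeric_col <- function(v, cn, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric cell in column '%s', row %d",
                 path, cn, bad[1L]), call. = FALSE)
  }
  if (anyNA(out)) {
    stop(sprintf("%s: missing value in column '%s'", path, cn), call. = FALSE)
  }
  out
}

#' @rdname read_spectra_csv
#' @param s,e,conc containers to write.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  df <- data.frame(sample_id = sample_ids(s), s$intensity,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- format_wl(s$wavelengths)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectra_csv
#' @export
write_emf_csv <- function(e, path) {
  stopifnot(inherits(e, "electrode_set"))
  df <- data.frame(sample_id = sample_ids(e), e$emf,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectra_csv
#' @export
write_conc_csv <- function(conc, path) {
  stopifnot(inherits(conc, "conc_vector"))
  utils::write.csv(as.data.frame(conc), path, row.names = FALSE)
  invisible(path)
}

#' Split samples into calibration and test sets
#'
#' `"rank_stratified"` (the default study design) orders the samples by
#' concentration, cuts the ranks into `n_test` contiguous blocks and draws
#' one test sample per block, so both sets span the full working range.
#' `"random"` draws the test set uniformly. Both are deterministic per seed
#' and return disjoint id sets.
#'
#' @param ids sample identifiers.
#' @param n_calib,n_test set sizes; `n_calib + n_test <= length(ids)`.
#' @param strategy `"rank_stratified"` or `"random"`.
#' @param seed integer seed.
#' @param conc [conc_vector] (or named numeric) required for
#'   `"rank_stratified"`.
#' @return list with `calib` and `test` character vectors.
#' @export
split_samples <- function(ids, n_calib, n_test,
                          strategy = c("rank_stratified", "random"),
                          seed = NULL, conc = NULL) {
  strategy <- match.arg(strategy)
  ids <- as.character(ids)
  n <- length(ids)
  if (n_calib < 0 || n_test < 0 || n_calib + n_test > n) {
    stop("argument error: n_calib + n_test exceeds the available samples",
         call. = FALSE)
  }
  test <- character(0)
  if (n_test > 0) {
    if (strategy == "rank_stratified") {
      if (is.null(conc)) {
        stop("rank_stratified split needs the concentration vector",
             call. = FALSE)
      }
      ord <- ids[order(as.numeric(conc[ids]))]
      blocks <- split(ord, cut(seq_len(n), breaks = n_test, labels = FALSE))
      test <- with_seed_opt(seed, vapply(blocks, function(b) {
        b[sample.int(length(b), 1L)]
      }, character(1)))
    } else {
      test <- with_seed_opt(seed, sample(ids, n_test))
    }
  }
  pool <- setdiff(ids, test)
  calib <- if (n_calib == length(pool)) pool else {
    with_seed_opt(if (is.null(seed)) NULL else seed + 1L,
                  sample(pool, n_calib))
  }
  list(calib = ids[ids %in% calib], test = ids[ids %in% test])
}
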