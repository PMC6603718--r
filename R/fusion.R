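#' Candidate hidden-node conditions for the PC-NN
#'
#' The seven two-hidden-layer architectures compared when tuning the fused
#' network (node counts, activation per layer, backprop learning rate). Case
#' 6 (30 logistic + 25 tanh nodes, rate 0.001) is the default architecture.
#'
#' @return data.frame with columns `case`, `nodes1`, `act1`, `nodes2`,
#'   `act2`, `learning_rate`.
#' @export
hidden_node_cases <- function() {
  data.frame(
    case = 1:7,
    nodes1 = c(30, 35, 30, 35, 35, 30, 25),
    act1 = c("logistic", "tanh", "tanh", "logistic", "relu", "logistic", "relu"),
    nodes2 = c(25, 25, 20, 30, 25, 25, 20),
    act2 = c("tanh", "relu", "logistic", "relu", "logistic", "tanh", "relu"),
    learning_rate = c(0.002, 0.001, 0.003, 0.001, 0.002, 0.001, 0.003),
    stringsAsFactors = FALSE
  )
}

#' Build a fused feature set from spectra and electrode readings
#'
#' Two feature-level fusion strategies:
#' * `"plsr_concat"` / `"pcr_concat"` (method A): the (optionally
#'   pretreated) spectra and the EMF columns are concatenated horizontally.
#' * `"pc_nn"` (method B): PCA is fitted on the calibration spectra only,
#'   the leading `n_pc` scores are concatenated with the EMF columns.
#'
#' Every data-dependent transform — the pretreatment, the PCA and the
#' per-column standardisation — is fitted exclusively on the rows named in
#' `fit_ids`; the remaining rows are only transformed. Columns are
#' z-standardised by default because PC scores and millivolt readings differ
#' by orders of magnitude; `scale = FALSE` keeps the literal unscaled
#' concatenation.
#'
#' @param spectra a [spectra_set].
#' @param emf an [electrode_set] with the same samples, or `NULL` for a
#'   spectra-only (NIR baseline) feature set.
#' @param method `"pc_nn"`, `"plsr_concat"` or `"pcr_concat"`.
#' @param n_pc number of PC score columns for `"pc_nn"` (default 11).
#' @param fit_ids sample ids of the calibration rows used to fit transforms;
#'   default all samples.
#' @param pretreatment pipeline spec string applied to the spectra before
#'   fusion (see [fit_pretreatment()]); default `"raw"`.
#' @param scale logical: z-standardise the fused columns (fit on `fit_ids`).
#' @return a `fusion_dataset`: features for all samples, per-column block
#'   labels (`"spectral"`/`"emf"`), frozen transforms and the fit ids.
#' @export
build_fusion <- function(spectra, emf = NULL,
                         method = c("pc_nn", "plsr_concat", "pcr_concat"),
                         n_pc = 11, fit_ids = NULL,
                         pretreatment = "raw", scale = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(spectra, "spectra_set"))
  ids <- sample_ids(spectra)
  if (!is.null(emf)) {
    stopifnot(inherits(emf, "electrode_set"))
    check_aligned(spectra, emf, "spectra and emf")
  }
  if (is.null(fit_ids)) fit_ids <- ids
  if (!all(fit_ids %in% ids)) {
    stop("fit_ids must be a subset of the sample ids", call. = FALSE)
  }
  calib_rows <- ids %in% fit_ids
  pre <- fit_pretreatment(spectra[calib_rows], pretreatment)
  sp_all <- predict(pre, spectra)
  pca <- NULL
  if (method == "pc_nn") {
    pca <- fit_pca(sp_all[calib_rows], n_pc)
    spec_block <- transform_scores(pca, sp_all)
    colnames(spec_block) <- paste0("PC", seq_len(n_pc))
  } else {
    spec_block <- sp_all$intensity
  }
  emf_block <- if (is.null(emf)) NULL else emf$emf
  features <- cbind(spec_block, emf_block)
  block_labels <- c(rep("spectral", ncol(spec_block)),
                    rep("emf", if (is.null(emf_block)) 0L else ncol(emf_block)))
  scaling <- NULL
  if (scale) {
    ctr <- colMeans(features[calib_rows, , drop = FALSE])
    scl <- apply(features[calib_rows, , drop = FALSE], 2L, stats::sd)
    scl <- ifelse(is.finite(scl) & scl > 0, scl, 1)
    scaling <- list(center = ctr, scale = scl)
    features <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  }
  rownames(features) <- ids
  structure(list(features = features, block_labels = block_labels,
                 method = method, n_pc = if (method == "pc_nn") n_pc else NA_integer_,
                 fit_ids = fit_ids, pretreat = pre, pca = pca,
                 scaling = scaling),
            class = "fusion_dataset")
}

#' @export
print.fusion_dataset <- function(x, ...) {
  cat(sprintf("<fusion_dataset> %s: %d samples x %d features (%d spectral + %d emf), %d calibration rows\n",
              x$method, nrow(x$features), ncol(x$features),
              sum(x$block_labels == "spectral"), sum(x$block_labels == "emf"),
              length(x$fit_ids)))
  invisible(x)
}

#' Fit a fusion calibration model
#'
#' Fits on the calibration rows of the fused dataset only. Concatenation
#' methods dispatch to [fit_plsr()] / [fit_pcr()], with the component count
#' either given (`model_cfg$k`) or chosen by 10-fold cross-validation on the
#' calibration rows. `"pc_nn"` trains a two-hidden-layer network on the
#' fused features; the architecture comes from [hidden_node_cases()]
#' (`model_cfg$case`, default 6) or an explicit `model_cfg$hidden` /
#' `model_cfg$activations` pair.
#'
#' @param fd a [build_fusion()] dataset.
#' @param y [conc_vector] (or named numeric) covering at least the fit rows.
#' @param model_cfg list of options: `k`, `k_grid`, `cv_folds`, `case`,
#'   `hidden`, `activations`, `algorithm` (`"lm"`/`"backprop"`),
#'   `max_epochs`, `seed`.
#' @return a `fusion_model`.
#' @export
fit_fusion <- function(fd, y, model_cfg = list()) {
  stopifnot(inherits(fd, "fusion_dataset"))
  ids <- rownames(fd$features)
  yv <- if (inherits(y, "conc_vector") || !is.null(names(y))) {
    if (!all(fd$fit_ids %in% names(y))) {
      stop("y does not cover all calibration samples", call. = FALSE)
    }
    as.numeric(y[fd$fit_ids])
  } else {
    if (length(y) != length(fd$fit_ids)) {
      stop("unnamed y must match the calibration rows in length", call. = FALSE)
    }
    as.numeric(y)
  }
  Xc <- fd$features[fd$fit_ids, , drop = FALSE]
  seed <- model_cfg$seed %||% 1L
  fit <- if (fd$method %in% c("plsr_concat", "pcr_concat")) {
    kind <- if (fd$method == "plsr_concat") "plsr" else "pcr"
    k <- model_cfg$k
    if (is.null(k)) {
      folds <- model_cfg$cv_folds %||% 10
      kmax <- min(nrow(Xc) - ceiling(nrow(Xc) / folds) - 1L, ncol(Xc), 15L)
      k_grid <- model_cfg$k_grid %||% seq_len(kmax)
      cv <- cross_validate(Xc, yv, k_grid, folds = folds, seed = seed,
                           method = kind)
      k <- attr(cv, "best_k")
    }
    if (kind == "plsr") fit_plsr(Xc, yv, k) else fit_pcr(Xc, yv, k)
  } else {
    cases <- hidden_node_cases()
    case <- model_cfg$case %||% 6L
    hidden <- model_cfg$hidden %||%
      c(cases$nodes1[case], cases$nodes2[case])
    acts <- model_cfg$activations %||%
      c(cases$act1[case], cases$act2[case])
    lr <- model_cfg$learning_rate %||% cases$learning_rate[case]
    net <- init_network(c(ncol(Xc), hidden, 1L), acts, seed = seed)
    cfg <- train_config(algorithm = model_cfg$algorithm %||% "lm",
                        learning_rate = lr,
                        max_epochs = model_cfg$max_epochs %||% 100L,
                        seed = seed)
    nn_train(net, Xc, yv, cfg)
  }
  structure(list(method = fd$method, fit = fit,
                 block_labels = fd$block_labels, n_pc = fd$n_pc,
                 fit_ids = fd$fit_ids, pretreat = fd$pretreat,
                 pca = fd$pca, scaling = fd$scaling),
            class = "fusion_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s fitted on %d calibration samples\n",
              x$method, length(x$fit_ids)))
  invisible(x)
}

# replay the frozen calibration-time transforms on new sensor data
fusion_features <- function(model, spectra, emf) {
  if (!any(model$block_labels == "emf")) emf <- NULL  # spectra-only model
  sp <- predict(model$pretreat, spectra)
  if (model$method == "pc_nn") {
    spec_block <- transform_scores(model$pca, sp)
  } else {
    spec_block <- sp$intensity
  }
  emf_block <- if (is.null(emf)) NULL else emf$emf
  features <- cbind(spec_block, emf_block)
  if (ncol(features) != length(model$block_labels)) {
    stop("feature blocks do not match the fitted fusion model", call. = FALSE)
  }
  if (!is.null(model$scaling)) {
    features <- sweep(sweep(features, 2L, model$scaling$center), 2L,
                      model$scaling$scale, "/")
  }
  features
}

#' @export
predict.fusion_model <- function(object, spectra, emf = NULL, ...) {
  feats <- fusion_features(object, spectra, emf)
  predict(object$fit, feats)
}

#' Evaluate a fusion model on a calibration/test split
#'
#' Computes [score_metrics()] on both sets. A leakage guard refuses to
#' evaluate when any test sample participated in fitting the model's
#' transforms (pretreatment, PCA, scalers) or weights.
#'
#' @param model a [fit_fusion()] model.
#' @param calib,test lists with elements `spectra`, `emf` (may be `NULL`)
#'   and `y` (a [conc_vector]).
#' @return list with `calibration` and `test` [score_metrics()] entries.
#' @export
evaluate_split <- function(model, calib, test) {
  stopifnot(inherits(model, "fusion_model"))
  test_ids <- sample_ids(test$spectra)
  overlap <- intersect(model$fit_ids, test_ids)
  same_set <- length(test_ids) == length(model$fit_ids) &&
    setequal(test_ids, model$fit_ids)
  if (length(overlap) && !same_set) {
    stop(sprintf("leakage guard: %d test sample(s) were used to fit the model (%s...)",
                 length(overlap), overlap[1]), call. = FALSE)
  }
  pred_cal <- predict(model, calib$spectra, calib$emf)
  pred_tst <- predict(model, test$spectra, test$emf)
  list(calibration = score_metrics(as.numeric(calib$y), pred_cal),
       test = score_metrics(as.numeric(test$y), pred_tst))
}
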