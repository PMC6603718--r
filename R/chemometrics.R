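as_feature_matrix <- function(x) {
  if (inherits(x, "spectra_set")) return(x$intensity)
  as.matrix(x)
}

#' Principal component analysis
#'
#' Mean-centres the columns (no variance scaling, the convention for spectral
#' data where the wavelength channels share units) and extracts the leading
#' `k` components by singular value decomposition.
#'
#' @param x feature matrix (samples x features) or [spectra_set].
#' @param k number of components, `1 <= k <= min(n_samples - 1, n_features)`.
#' @return a `latent_model` with `kind = "pca"`: centring vector, orthonormal
#'   loadings, training scores and per-component explained variance.
#' @export
fit_pca <- function(x, k) {
  x <- as_feature_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (!is.numeric(k) || k < 1 || k > kmax) {
    stop(sprintf("k must be in [1, %d]", kmax), call. = FALSE)
  }
  k <- as.integer(k)
  x_mean <- colMeans(x)
  xc <- sweep(x, 2L, x_mean)
  sv <- svd(xc, nu = 0, nv = kmax)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- xc %*% loadings
  structure(list(kind = "pca", n_components = k, x_mean = x_mean,
                 loadings = loadings, scores = scores,
                 explained_variance = sv$d[seq_len(kmax)]^2 / (n - 1),
                 singular_values = sv$d[seq_len(kmax)]),
            class = "latent_model")
}

#' Project new samples onto a fitted latent model
#'
#' Applies the centring and projection stored at fit time; nothing is refit
#' on the new data. For PCA/PCR the scores are `(x - x_mean) %*% loadings`;
#' for PLSR the NIPALS scores are reproduced through the equivalent direct
#' projection `(x - x_mean) %*% W (P'W)^-1`.
#'
#' @param model a fitted `latent_model`.
#' @param x new feature matrix or [spectra_set] with matching feature count.
#' @return score matrix (samples x components).
#' @export
transform_scores <- function(model, x) {
  stopifnot(inherits(model, "latent_model"))
  x <- as_feature_matrix(x)
  if (ncol(x) != length(model$x_mean)) {
    stop("shape error: feature count does not match the fitted model",
         call. = FALSE)
  }
  xc <- sweep(x, 2L, model$x_mean)
  if (model$kind == "plsr") {
    xc %*% model$rotation
  } else {
    xc %*% model$loadings
  }
}

#' Principal component regression
#'
#' PCA on the centred predictors followed by ordinary least squares of the
#' centred response on the leading `k` scores. The coefficient vector is
#' folded back to feature space so prediction is a single affine map.
#'
#' @inheritParams fit_pca
#' @param y numeric response (mg/L here), one value per sample.
#' @return a `latent_model` with `kind = "pcr"`, carrying `beta` (feature
#'   space) and `intercept`.
#' @export
fit_pcr <- function(x, y, k) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("y length must match sample count", call. = FALSE)
  pca <- fit_pca(x, k)
  yc <- y - mean(y)
  fit <- stats::lm.fit(pca$scores, yc)
  gamma <- fit$coefficients
  gamma[is.na(gamma)] <- 0  # rank-deficient trailing components carry no signal
  beta <- drop(pca$loadings %*% gamma)
  structure(list(kind = "pcr", n_components = pca$n_components,
                 x_mean = pca$x_mean, y_mean = mean(y),
                 loadings = pca$loadings, scores = pca$scores,
                 explained_variance = pca$explained_variance,
                 gamma = unname(gamma), beta = beta,
                 intercept = mean(y) - sum(pca$x_mean * beta)),
            class = "latent_model")
}

#' Partial least squares regression (NIPALS, univariate response)
#'
#' Classical NIPALS for a single response: per component, weights
#' `w = X'y / ||X'y||`, scores `t = Xw`, x-loadings `p = X't / t't`,
#' y-loading `q = y't / t't`, then deflation of `X` and `y`. The regression
#' vector is `beta = W (P'W)^-1 q`. For a univariate response each component
#' is available in closed form, so no within-component iteration is needed.
#'
#' @inheritParams fit_pcr
#' @return a `latent_model` with `kind = "plsr"` carrying weights `W`,
#'   x-loadings `P`, y-loadings `q`, the projection matrix `rotation =
#'   W (P'W)^-1`, `beta` and `intercept`.
#' @export
fit_plsr <- function(x, y, k) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("y length must match sample count", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (!is.numeric(k) || k < 1 || k > kmax) {
    stop(sprintf("k must be in [1, %d]", kmax), call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("degenerate: zero-variance response", call. = FALSE)
  k <- as.integer(k)
  x_mean <- colMeans(x); y_mean <- mean(y)
  Xc <- sweep(x, 2L, x_mean); yc <- y - y_mean
  W <- matrix(0, p, k); P <- matrix(0, p, k); q <- numeric(k)
  Tm <- matrix(0, n, k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {  # response fully deflated; later components are null
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]; Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      k <- a - 1L
      break
    }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; Tm[, a] <- t_
  }
  rotation <- W %*% solve(crossprod(P, W))
  beta <- drop(rotation %*% q)
  structure(list(kind = "plsr", n_components = k, x_mean = x_mean,
                 y_mean = y_mean, weights = W, x_loadings = P,
                 y_loadings = q, rotation = rotation, scores = Tm,
                 beta = beta,
                 intercept = y_mean - sum(x_mean * beta)),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> %s, %d component(s), %d feature(s)\n",
              toupper(x$kind), x$n_components, length(x$x_mean)))
  invisible(x)
}

#' @export
predict.latent_model <- function(object, newdata, ...) {
  if (object$kind == "pca") {
    stop("a plain PCA model has no response to predict; use transform_scores()",
         call. = FALSE)
  }
  x <- as_feature_matrix(newdata)
  if (ncol(x) != length(object$x_mean)) {
    stop("shape error: feature count does not match the fitted model",
         call. = FALSE)
  }
  drop(x %*% object$beta) + object$intercept
}

#' K-fold cross-validation over component counts
#'
#' Samples are shuffled into `folds` folds under the given seed; for each
#' candidate component count the out-of-fold predictions are pooled across
#' folds and scored once. The selected count minimises CV RMSE (or maximises
#' CV R-squared with `select = "r2"`); near-ties within a relative tolerance
#' of 1e-8 resolve to the smaller count, so on effectively noiseless data the
#' most parsimonious adequate model wins.
#'
#' @param x feature matrix or [spectra_set].
#' @param y numeric response.
#' @param k_grid candidate component counts.
#' @param folds number of folds (default 10; `folds = n` is leave-one-out).
#' @param seed integer seed for the fold shuffle.
#' @param method `"pcr"` or `"plsr"`.
#' @param select metric used for selection, `"rmse"` or `"r2"`.
#' @return data.frame with columns `k`, `cv_r2`, `cv_rmse`; the chosen count
#'   is in `attr(, "best_k")`.
#' @export
cross_validate <- function(x, y, k_grid, folds = 10, seed = NULL,
                           method = c("pcr", "plsr"),
                           select = c("rmse", "r2")) {
  method <- match.arg(method)
  select <- match.arg(select)
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (folds < 2 || folds > n) {
    stop("folds must be in [2, n_samples]", call. = FALSE)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  min_train <- n - ceiling(n / folds)
  kmax <- min(min_train - 1L, ncol(x))
  if (max(k_grid) > kmax) {
    stop(sprintf("max(k_grid) = %d not feasible in every training fold (max %d)",
                 max(k_grid), kmax), call. = FALSE)
  }
  assign_ <- with_seed_opt(seed, sample(rep_len(seq_len(folds), n)))
  fit_fun <- if (method == "pcr") fit_pcr else fit_plsr
  res <- lapply(k_grid, function(k) {
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      hold <- assign_ == f
      m <- fit_fun(x[!hold, , drop = FALSE], y[!hold], k)
      pred[hold] <- predict(m, x[hold, , drop = FALSE])
    }
    met <- score_metrics(y, pred)
    data.frame(k = k, cv_r2 = met$r2, cv_rmse = met$rmse)
  })
  tab <- do.call(rbind, res)
  crit <- if (select == "rmse") tab$cv_rmse else -tab$cv_r2
  # near-ties resolve to the smaller k; the tolerance is on the response
  # scale so that numerically-zero CV errors compare as equal
  tol <- if (select == "rmse") 1e-8 * stats::sd(y) else 1e-8
  best_k <- tab$k[which(crit <= min(crit) + tol)[1L]]
  attr(tab, "best_k") <- best_k
  attr(tab, "seed") <- seed
  tab
}

#' Calibration metrics
#'
#' Scores predictions the way calibration studies report them: coefficient
#' of determination `R2 = 1 - SSE/SST` evaluated on the set at hand (not a
#' squared correlation, so test-set values can be negative), root mean
#' square error in response units, and the slope/offset of the ordinary
#' least squares line of predicted on actual.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return a `calibration_metrics` list: `r2`, `rmse`, `slope`, `offset`, `n`.
#' @export
score_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (n < 2L || length(y_pred) != n) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("r2 undefined for constant y_true", call. = FALSE)
  sse <- sum((y_true - y_pred)^2)
  line <- stats::lm.fit(cbind(1, y_true), y_pred)$coefficients
  structure(list(r2 = 1 - sse / sst, rmse = sqrt(sse / n),
                 slope = unname(line[2]), offset = unname(line[1]), n = n),
            class = "calibration_metrics")
}

#' @export
print.calibration_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.4g, slope = %.3f, offset = %.3f (n = %d)\n",
              x$r2, x$rmse, x$slope, x$offset, x$n))
  invisible(x)
}
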