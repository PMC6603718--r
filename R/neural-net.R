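#' Hidden-node activation functions
#'
#' The three activations used in the calibration networks: logistic
#' `1/(1+exp(-x))`, hyperbolic tangent `2/(1+exp(-2x)) - 1` and ReLU
#' `max(0, x)`. Derivatives are `f(1-f)`, `1 - f^2` and the 0/1 step
#' respectively; the ReLU derivative at exactly 0 is taken as 1 (a
#' measure-zero tie-break).
#'
#' @param tag one of `"logistic"`, `"tanh"`, `"relu"`.
#' @param x numeric input (vectorised).
#' @return `activation()`: f(x); `activation_deriv()`: f'(x).
#' @export
activation <- function(tag, x) {
  switch(tag,
    logistic = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    relu = pmax(x, 0),
    stop("unknown activation tag: ", tag, call. = FALSE))
}

#' @rdname activation
#' @export
activation_deriv <- function(tag, x) {
  switch(tag,
    logistic = { f <- 1 / (1 + exp(-x)); f * (1 - f) },
    tanh = 1 - tanh(x)^2,
    relu = as.numeric(x >= 0),
    stop("unknown activation tag: ", tag, call. = FALSE))
}

# derivative expressed through the already-computed activation value
act_deriv_from_value <- function(tag, z, a) {
  switch(tag,
    logistic = a * (1 - a),
    tanh = 1 - a^2,
    relu = (z >= 0) * 1)
}

#' Initialise a feed-forward network
#'
#' Fully connected network with linear output. Weights are drawn
#' `N(0, 1/fan_in)` under the given seed; biases start at zero. Input and
#' response standardisation parameters start as identity and are fitted by
#' [nn_train()].
#'
#' @param layer_sizes integer vector of node counts, input first, output
#'   last (length >= 2; the calibration networks use two hidden layers).
#' @param activations character vector of hidden-layer activation tags,
#'   length `length(layer_sizes) - 2`.
#' @param seed integer seed for the weight draw.
#' @return a `network_model`.
#' @export
init_network <- function(layer_sizes, activations = character(0), seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must have >= 2 entries, all >= 1", call. = FALSE)
  }
  n_hidden <- length(layer_sizes) - 2L
  if (length(activations) != n_hidden) {
    stop(sprintf("need %d hidden activation tag(s)", n_hidden), call. = FALSE)
  }
  for (tag in activations) activation(tag, 0)  # validates the tag
  weights <- with_seed_opt(seed, lapply(seq_len(length(layer_sizes) - 1L),
    function(l) {
      fan_in <- layer_sizes[l]
      W <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L], 0,
                               1 / sqrt(fan_in)),
                  fan_in, layer_sizes[l + 1L])
      rbind(0, W)  # first row: bias
    }))
  structure(list(layer_sizes = layer_sizes, activations = activations,
                 weights = weights,
                 x_center = rep(0, layer_sizes[1]),
                 x_scale = rep(1, layer_sizes[1]),
                 y_center = 0, y_scale = 1,
                 seed = as.integer(seed), trained = FALSE,
                 loss_trace = numeric(0)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %s, activations [%s], %s\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$activations, collapse = ", "),
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$loss_trace)) else "untrained"))
  invisible(x)
}

# propagate standardized inputs; returns pre-activations, activations, output
nn_forward_std <- function(net, Xs) {
  L <- length(net$weights)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- Xs
  for (l in seq_len(L)) {
    Z[[l]] <- cbind(1, A[[l]]) %*% net$weights[[l]]
    A[[l + 1L]] <- if (l < L) {
      activation(net$activations[l], Z[[l]])
    } else {
      Z[[l]]  # linear output
    }
  }
  list(A = A, Z = Z, yhat = A[[L + 1L]])
}

standardize_x <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$layer_sizes[1]) {
    stop("shape error: input feature count does not match the network",
         call. = FALSE)
  }
  sweep(sweep(x, 2L, net$x_center), 2L, net$x_scale, "/")
}

#' Network forward pass
#'
#' Standardises the inputs with the stored scalers, propagates through the
#' hidden activations and the linear output node, and de-standardises the
#' response.
#'
#' @param net a `network_model`.
#' @param x feature matrix (samples x input nodes).
#' @return numeric vector of predictions in response units.
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "network_model"))
  fw <- nn_forward_std(net, standardize_x(net, x))
  drop(fw$yhat) * net$y_scale + net$y_center
}

#' @export
predict.network_model <- function(object, newdata, ...) {
  nn_forward(object, newdata)
}

#' Network loss and gradient
#'
#' `nn_loss()` is the half sum of squared errors in standardised response
#' units, `0.5 * sum((yhat_std - y_std)^2)`; `nn_gradient()` returns its
#' exact reverse-mode gradient, one matrix per weight layer (bias row
#' first), matching the weight layout of the network.
#'
#' @param net a `network_model`.
#' @param x feature matrix.
#' @param y numeric response vector.
#' @return `nn_loss()`: scalar; `nn_gradient()`: list of gradient matrices.
#' @export
nn_loss <- function(net, x, y) {
  ys <- (as.numeric(y) - net$y_center) / net$y_scale
  fw <- nn_forward_std(net, standardize_x(net, x))
  0.5 * sum((drop(fw$yhat) - ys)^2)
}

#' @rdname nn_loss
#' @export
nn_gradient <- function(net, x, y) {
  ys <- (as.numeric(y) - net$y_center) / net$y_scale
  Xs <- standardize_x(net, x)
  if (length(ys) != nrow(Xs)) stop("shape error: y length", call. = FALSE)
  fw <- nn_forward_std(net, Xs)
  backprop_deltas(net, fw, matrix(drop(fw$yhat) - ys, ncol = 1L))$grads
}

# shared reverse sweep: given output-layer delta (n x n_out), return
# per-layer weight gradients and per-layer deltas
backprop_deltas <- function(net, fw, delta_out) {
  L <- length(net$weights)
  grads <- vector("list", L)
  deltas <- vector("list", L)
  delta <- delta_out
  for (l in rev(seq_len(L))) {
    deltas[[l]] <- delta
    grads[[l]] <- crossprod(cbind(1, fw$A[[l]]), delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$weights[[l]][-1L, , drop = FALSE])) *
        act_deriv_from_value(net$activations[l - 1L],
                             fw$Z[[l - 1L]], fw$A[[l]])
    }
  }
  list(grads = grads, deltas = deltas)
}

flatten_weights <- function(weights) unlist(lapply(weights, as.vector))

unflatten_weights <- function(w, template) {
  off <- 0L
  lapply(template, function(W) {
    k <- length(W)
    out <- matrix(w[off + seq_len(k)], nrow(W), ncol(W))
    off <<- off + k
    out
  })
}

# Jacobian of standardized residuals wrt the flattened weights (n x p).
# For the single linear output node, row i is d yhat_i / d w via a reverse
# sweep seeded with 1.
nn_jacobian <- function(net, Xs) {
  n <- nrow(Xs)
  fw <- nn_forward_std(net, Xs)
  bp <- backprop_deltas(net, fw, matrix(1, n, 1L))
  L <- length(net$weights)
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    Aprev <- cbind(1, fw$A[[l]])             # n x (m+1)
    D <- bp$deltas[[l]]                       # n x k
    m1 <- ncol(Aprev); k <- ncol(D)
    # column-major layout of W[[l]]: entry (r, c) sits at (c-1)*m1 + r
    blocks[[l]] <- Aprev[, rep(seq_len(m1), times = k), drop = FALSE] *
      D[, rep(seq_len(k), each = m1), drop = FALSE]
  }
  list(J = do.call(cbind, blocks), yhat = drop(fw$yhat))
}

#' Training configuration
#'
#' @param algorithm `"lm"` (Levenberg-Marquardt, the default) or
#'   `"backprop"` (full-batch gradient descent with momentum).
#' @param learning_rate step size for backprop mode (ignored under LM).
#' @param momentum momentum coefficient in `[0, 1)` (backprop mode).
#' @param max_epochs iteration cap (LM counts accepted or rejected damping
#'   cycles; backprop counts gradient steps).
#' @param lm_lambda0 initial LM damping; `lm_up`/`lm_down` are the
#'   multiplicative factors applied on rejected/accepted steps.
#' @param tol early-stop threshold: training stops once the loss improves by
#'   less than `tol` for `patience` consecutive epochs.
#' @param patience consecutive low-improvement epochs tolerated.
#' @param seed recorded for provenance (training itself is deterministic
#'   given the initial weights).
#' @return a `train_config` list.
#' @export
train_config <- function(algorithm = c("lm", "backprop"),
                         learning_rate = 0.001, momentum = 0.9,
                         max_epochs = NULL, lm_lambda0 = 1e-3,
                         lm_up = 10, lm_down = 10,
                         tol = 1e-9, patience = 20, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)", call. = FALSE)
  if (is.null(max_epochs)) {
    max_epochs <- if (algorithm == "lm") 200L else 1000L
  }
  if (max_epochs < 0) stop("max_epochs must be >= 0", call. = FALSE)
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 lm_lambda0 = lm_lambda0, lm_up = lm_up, lm_down = lm_down,
                 tol = tol, patience = as.integer(patience), seed = seed),
            class = "train_config")
}

#' Train a network
#'
#' Fits the input/response standardisation on the training data, then trains
#' the weights by the configured algorithm. Backprop mode performs
#' full-batch gradient descent on the mean squared error with momentum. LM
#' mode updates `delta_w = -(J'J + lambda I)^-1 J'r` on the standardised
#' residual vector `r`, accepting a step only when the loss decreases
#' (`lambda` is divided by `lm_down` on acceptance, multiplied by `lm_up` on
#' rejection), so the accepted-step loss sequence is non-increasing by
#' construction. With `max_epochs = 0` the initial weights are returned
#' unchanged. A run whose loss becomes non-finite aborts with an error
#' carrying the loss trace.
#'
#' @param net an initialised `network_model`.
#' @param x feature matrix (samples x input nodes).
#' @param y numeric response vector.
#' @param cfg a [train_config()].
#' @return the trained `network_model`; the per-epoch standardised MSE is in
#'   `$loss_trace`.
#' @export
nn_train <- function(net, x, y, cfg = train_config()) {
  stopifnot(inherits(net, "network_model"), inherits(cfg, "train_config"))
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) < 1L || length(y) != nrow(x)) {
    stop("need >= 1 sample with matching y", call. = FALSE)
  }
  # fit scalers on the training data (constant columns keep unit scale)
  net$x_center <- colMeans(x)
  xsd <- apply(x, 2L, stats::sd)
  if (nrow(x) == 1L) xsd <- rep(1, ncol(x))
  net$x_scale <- ifelse(is.finite(xsd) & xsd > 0, xsd, 1)
  ysd <- if (nrow(x) > 1L) stats::sd(y) else 1
  net$y_center <- mean(y)
  net$y_scale <- if (is.finite(ysd) && ysd > 0) ysd else 1

  Xs <- standardize_x(net, x)
  ys <- (y - net$y_center) / net$y_scale
  n <- length(ys)
  if (cfg$max_epochs == 0L) {
    net$loss_trace <- numeric(0)
    return(net)
  }
  net <- if (cfg$algorithm == "backprop") {
    train_backprop(net, Xs, ys, cfg)
  } else {
    train_lm(net, Xs, ys, cfg)
  }
  net$trained <- TRUE
  net
}

train_backprop <- function(net, Xs, ys, cfg) {
  n <- length(ys)
  velocity <- lapply(net$weights, function(W) W * 0)
  trace <- numeric(0)
  stall <- 0L
  prev <- Inf
  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- nn_forward_std(net, Xs)
    r <- drop(fw$yhat) - ys
    loss <- mean(r^2)
    if (!is.finite(loss)) {
      stop_divergence(trace)
    }
    grads <- backprop_deltas(net, fw, matrix(r / n, ncol = 1L))$grads
    for (l in seq_along(net$weights)) {
      velocity[[l]] <- cfg$momentum * velocity[[l]] -
        cfg$learning_rate * grads[[l]]
      net$weights[[l]] <- net$weights[[l]] + velocity[[l]]
    }
    trace <- c(trace, loss)
    if (prev - loss < cfg$tol) stall <- stall + 1L else stall <- 0L
    if (stall >= cfg$patience) break
    prev <- loss
  }
  net$loss_trace <- trace
  net
}

train_lm <- function(net, Xs, ys, cfg) {
  n <- length(ys)
  w <- flatten_weights(net$weights)
  p <- length(w)
  lambda <- cfg$lm_lambda0
  jb <- nn_jacobian(net, Xs)
  r <- jb$yhat - ys
  loss <- mean(r^2)
  if (!is.finite(loss)) stop_divergence(numeric(0))
  trace <- loss
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    H <- crossprod(jb$J)
    g <- crossprod(jb$J, r)
    accepted <- FALSE
    while (!accepted && lambda < 1e12) {
      step <- tryCatch(solve(H + lambda * diag(p), g), error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w - drop(step)
        net_try <- net
        net_try$weights <- unflatten_weights(w_new, net$weights)
        r_try <- drop(nn_forward_std(net_try, Xs)$yhat) - ys
        loss_try <- mean(r_try^2)
        if (is.finite(loss_try) && loss_try < loss) {
          accepted <- TRUE
          w <- w_new; net <- net_try; r <- r_try
          jb <- nn_jacobian(net, Xs)
          improvement <- loss - loss_try
          loss <- loss_try
          lambda <- lambda / cfg$lm_down
          trace <- c(trace, loss)
          if (improvement < cfg$tol) stall <- stall + 1L else stall <- 0L
          break
        }
      }
      lambda <- lambda * cfg$lm_up
    }
    if (!accepted) break        # damping exhausted: local minimum reached
    if (stall >= cfg$patience) break
  }
  net$loss_trace <- trace
  net
}

stop_divergence <- function(trace) {
  cond <- structure(class = c("hydrofuse_divergence", "error", "condition"),
                    list(message = "training diverged (non-finite loss)",
                         call = NULL, trace = trace))
  stop(cond)
}
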