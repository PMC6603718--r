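# Independent oracles used to cross-check the package's own implementations.
# These deliberately share no code with the R/ sources.

# Ordinary least squares predictions (QR, with intercept).
ols_predict <- function(x, y, xnew = x) {
  fit <- stats::lm.fit(cbind(1, as.matrix(x)), y)
  drop(cbind(1, as.matrix(xnew)) %*% fit$coefficients)
}

# SIMPLS (de Jong 1993) for a univariate response. For a single y, SIMPLS
# and NIPALS span the same score space, so fitted values must agree.
simpls_predict <- function(x, y, k, xnew = x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x); ym <- mean(y)
  X0 <- sweep(x, 2L, xm); y0 <- y - ym
  s <- crossprod(X0, y0)
  R <- matrix(0, p, k); V <- matrix(0, p, k); q <- numeric(k)
  for (a in seq_len(k)) {
    r <- s
    t_ <- drop(X0 %*% r)
    t_ <- t_ - mean(t_)
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt; r <- r / nt
    p_ <- crossprod(X0, t_)
    q[a] <- sum(y0 * t_)
    v <- p_
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; V[, a] <- v
  }
  beta <- drop(R %*% q)
  drop(sweep(as.matrix(xnew), 2L, xm) %*% beta) + ym
}

# Central finite-difference gradient of nn_loss over every weight.
nn_fd_gradient <- function(net, x, y, h = 1e-6) {
  lapply(seq_along(net$weights), function(l) {
    W <- net$weights[[l]]
    G <- W
    for (i in seq_len(nrow(W))) {
      for (j in seq_len(ncol(W))) {
        np <- net; np$weights[[l]][i, j] <- W[i, j] + h
        nm <- net; nm$weights[[l]][i, j] <- W[i, j] - h
        G[i, j] <- (nn_loss(np, x, y) - nn_loss(nm, x, y)) / (2 * h)
      }
    }
    G
  })
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / (abs(b) + floor))
}
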