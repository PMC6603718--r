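test_that("activation functions and derivatives take their textbook values", {
  expect_equal(activation("logistic", 0), 0.5)
  expect_equal(activation_deriv("logistic", 0), 0.25)
  expect_equal(activation("tanh", 0), 0)
  expect_equal(activation_deriv("tanh", 0), 1)
  expect_equal(activation("relu", -3), 0)
  expect_equal(activation("relu", 2), 2)
  expect_equal(activation_deriv("relu", c(-1, 0, 1)), c(0, 1, 1))
  # tanh derivative is 1 - f^2 (not the arctangent derivative)
  z <- 0.7
  expect_equal(activation_deriv("tanh", z), 1 - tanh(z)^2, tolerance = 1e-12)
  expect_error(activation("softplus", 1), "unknown activation")
})

test_that("initialisation is seeded and scales with fan-in", {
  a <- init_network(c(4, 6, 5, 1), c("tanh", "logistic"), seed = 9)
  b <- init_network(c(4, 6, 5, 1), c("tanh", "logistic"), seed = 9)
  d <- init_network(c(4, 6, 5, 1), c("tanh", "logistic"), seed = 10)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, d$weights))
  expect_error(init_network(c(3, 0, 1), "tanh"), ">= 1")

  # empirical weight sd tracks 1/sqrt(fan_in)
  sds <- vapply(c(4, 64), function(fi) {
    ws <- unlist(lapply(1:100, function(s) {
      init_network(c(fi, 8, 1), "tanh", seed = s)$weights[[1]][-1, ]
    }))
    stats::sd(ws)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], sqrt(64 / 4), tolerance = 0.15)
})

test_that("forward pass matches hand-computed propagation", {
  # 2-2-1 net with fixed weights, logistic hidden layer, identity scalers
  net <- init_network(c(2, 2, 1), "logistic", seed = 1)
  net$weights[[1]] <- rbind(c(0.1, -0.2), c(0.5, 0.3), c(-0.4, 0.8))
  net$weights[[2]] <- rbind(0.2, c(1.5), c(-0.7))
  x <- matrix(c(1, 2), 1, 2)
  z1 <- c(0.1 + 0.5 * 1 - 0.4 * 2, -0.2 + 0.3 * 1 + 0.8 * 2)
  a1 <- 1 / (1 + exp(-z1))
  manual <- 0.2 + 1.5 * a1[1] - 0.7 * a1[2]
  expect_equal(nn_forward(net, x), manual, tolerance = 1e-12)

  # a single linear pathway reproduces an affine function exactly
  lin <- init_network(c(1, 1), character(0), seed = 1)
  lin$weights[[1]] <- rbind(2.5, -3)
  expect_equal(nn_forward(lin, matrix(c(0, 1, 2), 3, 1)),
               2.5 - 3 * c(0, 1, 2), tolerance = 1e-12)

  # zero weights: constant prediction from the de-standardised output bias
  net0 <- init_network(c(3, 4, 2, 1), c("tanh", "tanh"), seed = 2)
  net0$weights <- lapply(net0$weights, function(W) W * 0)
  net0$y_center <- 50; net0$y_scale <- 10
  expect_equal(nn_forward(net0, matrix(rnorm(9), 3, 3)), rep(50, 3))
  expect_error(nn_forward(net0, matrix(1, 1, 2)), "shape error")
})

test_that("backprop gradients vanish at a perfect fit and match finite differences", {
  lin <- init_network(c(1, 1), character(0), seed = 1)
  lin$weights[[1]] <- rbind(0.5, 2)
  x <- matrix(c(-1, 0, 2), 3, 1)
  g0 <- nn_gradient(lin, x, 0.5 + 2 * drop(x))
  expect_equal(unlist(g0), rep(0, 2), tolerance = 1e-12)

  for (acts in list(c("logistic", "tanh"), c("tanh", "relu"),
                    c("relu", "logistic"))) {
    net <- init_network(c(3, 4, 3, 1), acts, seed = 17)
    withr::with_seed(18, {
      x <- matrix(rnorm(24), 8, 3)
      y <- rnorm(8)
    })
    g <- nn_gradient(net, x, y)
    fd <- nn_fd_gradient(net, x, y)
    expect_lt(max_rel_err(unlist(g), unlist(fd)), 1e-6)
  }
})

test_that("training contract: zero epochs, determinism, divergence error", {
  withr::with_seed(41, {
    x <- matrix(rnorm(60), 30, 2)
    y <- drop(x %*% c(1, -2)) + 3
  })
  net <- init_network(c(2, 4, 3, 1), c("tanh", "tanh"), seed = 5)
  un <- nn_train(net, x, y, train_config("lm", max_epochs = 0))
  expect_identical(un$weights, net$weights)  # weights untouched

  t1 <- nn_train(net, x, y, train_config("lm", max_epochs = 30))
  t2 <- nn_train(net, x, y, train_config("lm", max_epochs = 30))
  expect_identical(t1$weights, t2$weights)
  expect_identical(t1$loss_trace, t2$loss_trace)

  net_r <- init_network(c(2, 4, 3, 1), c("relu", "relu"), seed = 5)
  err <- tryCatch(
    nn_train(net_r, x, y, train_config("backprop", learning_rate = 1e8,
                                       max_epochs = 200)),
    error = function(e) e)
  expect_s3_class(err, "hydrofuse_divergence")
  expect_true(is.numeric(err$trace))
})

test_that("LM reaches the analytic optimum of a linear problem in few steps", {
  # affine net => residuals linear in weights => Gauss-Newton step is exact
  withr::with_seed(42, {
    x <- matrix(rnorm(40), 40, 1)
    y <- 2 * drop(x) - 1
  })
  net <- init_network(c(1, 1), character(0), seed = 3)
  tr <- nn_train(net, x, y, train_config("lm", max_epochs = 5))
  coefs <- stats::coef(stats::lm(y ~ x))
  # trained net reproduces the OLS line
  expect_equal(nn_forward(tr, x), drop(cbind(1, x) %*% coefs),
               tolerance = 1e-6)
  expect_lte(length(tr$loss_trace), 6)  # initial loss + <= 5 accepted steps
  expect_true(all(diff(tr$loss_trace) <= 0))
})

test_that("LM solves a noiseless linear task through a nonlinear net", {
  withr::with_seed(43, {
    x <- matrix(rnorm(150), 50, 3)
    y <- drop(x %*% c(2, -1, 0.5)) + 4
  })
  net <- init_network(c(3, 6, 4, 1), c("tanh", "tanh"), seed = 11)
  tr <- nn_train(net, x, y, train_config("lm", max_epochs = 150))
  rmse_std <- sqrt(mean(((nn_forward(tr, x) - y) / tr$y_scale)^2))
  expect_lt(rmse_std, 1e-3)
  expect_true(all(diff(tr$loss_trace) <= 0))
})

test_that("backprop with momentum descends on the mean squared error", {
  withr::with_seed(44, {
    x <- matrix(rnorm(100), 50, 2)
    y <- drop(x %*% c(1, 1))
  })
  net <- init_network(c(2, 5, 4, 1), c("logistic", "tanh"), seed = 6)
  tr <- nn_train(net, x, y, train_config("backprop", learning_rate = 0.05,
                                         momentum = 0.9, max_epochs = 400))
  expect_lt(utils::tail(tr$loss_trace, 1), tr$loss_trace[1] / 10)
})

test_that("a tanh network approximates a smooth 1-D function", {
  withr::with_seed(45, x <- matrix(sort(runif(200, -3, 3)), 200, 1))
  y <- sin(drop(x)) + 0.3 * drop(x)
  net <- init_network(c(1, 10, 8, 1), c("tanh", "tanh"), seed = 7)
  tr <- nn_train(net, x, y, train_config("lm", max_epochs = 120))
  expect_gte(score_metrics(y, nn_forward(tr, x))$r2, 0.99)
})
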