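toy_regression <- function(n = 200, d = 8, seed = 2) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * d), n, d)
  y <- X[, 1] - 0.5 * X[, 2] + 0.1 * stats::rnorm(n)
  list(X = X, y = y)
}

fast_cfg <- function(...) {
  args <- utils::modifyList(list(hidden = 16, n_layers = 3,
                                 max_epochs = 120, lr = 1e-2,
                                 dropout = 0.1),
                            list(...))
  do.call(mlp_config, args)
}

test_that("constant targets warn and are fitted to within 1%", {
  set.seed(1)
  X <- matrix(stats::rnorm(450), 150, 3)
  expect_warning(
    net <- mlp_train(X[1:100, ], matrix(2, 100, 1),
                     fast_cfg(dropout = 0, max_epochs = 800,
                              patience = 30),
                     loss = "mse", seed = 1),
    "degenerate_target")
  pred <- mlp_predict(net, X[101:150, ])
  expect_true(all(abs(pred - 2) < 2 * 1e-2))
})

test_that("training is deterministic under a fixed seed", {
  d <- toy_regression()
  a <- mlp_train(d$X, matrix(d$y), fast_cfg(), loss = "mse", seed = 9)
  b <- mlp_train(d$X, matrix(d$y), fast_cfg(), loss = "mse", seed = 9)
  expect_identical(a$W, b$W)
  expect_identical(a$val_loss, b$val_loss)
})

test_that("the regressor learns a simple signal", {
  d <- toy_regression(400)
  net <- mlp_train(d$X, matrix(d$y), fast_cfg(), loss = "mse", seed = 3)
  ho <- toy_regression(200, seed = 99)
  m <- regression_metrics(ho$y, as.numeric(mlp_predict(net, ho$X)))
  expect_gte(m$r_squared, 0.8)
})

test_that("softmax head returns a distribution; bce head stays in (0,1)", {
  set.seed(4)
  X <- rbind(matrix(stats::rnorm(200, 0), 100, 2),
             matrix(stats::rnorm(200, 3), 100, 2))
  Y <- rbind(matrix(rep(c(1, 0), each = 100), 100, 2, byrow = FALSE),
             matrix(rep(c(0, 1), each = 100), 100, 2, byrow = FALSE))
  Y <- cbind(rep(c(1, 0), each = 100), rep(c(0, 1), each = 100))
  net <- mlp_train(X, Y, fast_cfg(), loss = "softmax_ce", seed = 2)
  P <- mlp_predict(net, X)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-6)
  netb <- mlp_train(X, Y, fast_cfg(), loss = "bce", seed = 2)
  Pb <- mlp_predict(netb, X)
  expect_true(all(Pb > 0 & Pb < 1))
  expect_gte(mean((Pb[, 2] > 0.5) == (Y[, 2] == 1)), 0.9)
})

test_that("layer and batch normalization variants train", {
  d <- toy_regression(150)
  for (opt in list(list(layer_norm = TRUE), list(batch_norm = TRUE))) {
    net <- mlp_train(d$X, matrix(d$y),
                     do.call(fast_cfg, opt), loss = "mse", seed = 5)
    expect_true(all(is.finite(mlp_predict(net, d$X))))
  }
})

test_that("duplicating every example leaves hard predictions unchanged", {
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(120, 0), 60, 2),
             matrix(stats::rnorm(120, 4), 60, 2))
  Y <- cbind(rep(c(1, 0), each = 60), rep(c(0, 1), each = 60))
  probe <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
                 matrix(stats::rnorm(40, 4), 20, 2))
  net1 <- mlp_train(X, Y, fast_cfg(dropout = 0), loss = "softmax_ce",
                    seed = 7)
  net2 <- mlp_train(X[rep(1:120, 2), ], Y[rep(1:120, 2), ],
                    fast_cfg(dropout = 0), loss = "softmax_ce", seed = 7)
  h1 <- apply(mlp_predict(net1, probe), 1, which.max)
  h2 <- apply(mlp_predict(net2, probe), 1, which.max)
  expect_identical(h1, h2)
})

test_that("inference-time dropout is stochastic and seed-controlled", {
  d <- toy_regression(150)
  net <- mlp_train(d$X, matrix(d$y), fast_cfg(dropout = 0.3),
                   loss = "mse", seed = 3)
  det <- mlp_predict(net, d$X[1:5, ])
  set.seed(1); a <- mlp_predict(net, d$X[1:5, ], mc_dropout = TRUE)
  set.seed(1); b <- mlp_predict(net, d$X[1:5, ], mc_dropout = TRUE)
  set.seed(2); c_ <- mlp_predict(net, d$X[1:5, ], mc_dropout = TRUE)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_false(identical(a, det))
})
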