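# Minimal feed-forward network engine (matrix ops + Adam) used for the
# five-layer category predictor and nutrient-density regressors. Losses:
# mean squared error (linear head), softmax cross-entropy against soft
# targets, and per-class sigmoid BCE. Supports dropout (also at
# inference for MC-dropout intervals), L2 regularization, decoupled
# weight decay, input / layer / batch normalization, and early stopping
# with best-weight restore on a 20% validation split.

#' Network training configuration
#'
#' Defaults follow the tested hyperparameter grid: 5 layers, 256 nodes
#' per hidden layer, ReLU, dropout 0.2, L2 lambda 1e-3, Adam learning
#' rate 1e-3, input normalization on, layer/batch normalization off,
#' early stopping with patience 10 on a 20% validation split.
#'
#' @param n_layers total weight layers (input, hidden..., output).
#' @param hidden nodes per hidden layer.
#' @param activation `"relu"` or `"leaky_relu"`.
#' @param leaky_alpha slope for leaky ReLU.
#' @param dropout dropout rate on hidden activations.
#' @param l2 L2 regularization lambda (added to gradients).
#' @param weight_decay decoupled weight decay (used for fine-tuning).
#' @param lr Adam learning rate.
#' @param input_norm standardize inputs using training statistics.
#' @param layer_norm,batch_norm normalize hidden pre-activations.
#' @param max_epochs,patience early-stopping schedule.
#' @param val_frac validation fraction for early stopping.
#' @param batch_size minibatch size (default 32); `NULL` = full batch.
#' @return list of class `mint_mlp_config`.
#' @export
mlp_config <- function(n_layers = 5, hidden = 256,
                       activation = c("relu", "leaky_relu"),
                       leaky_alpha = 0.01, dropout = 0.2, l2 = 1e-3,
                       weight_decay = 0, lr = 1e-3, input_norm = TRUE,
                       layer_norm = FALSE, batch_norm = FALSE,
                       max_epochs = 500, patience = 10, val_frac = 0.2,
                       batch_size = 32) {
  structure(list(
    n_layers = n_layers, hidden = hidden,
    activation = match.arg(activation), leaky_alpha = leaky_alpha,
    dropout = dropout, l2 = l2, weight_decay = weight_decay, lr = lr,
    input_norm = input_norm, layer_norm = layer_norm,
    batch_norm = batch_norm, max_epochs = max_epochs,
    patience = patience, val_frac = val_frac, batch_size = batch_size
  ), class = "mint_mlp_config")
}

act_fun <- function(z, cfg) {
  if (cfg$activation == "relu") pmax(z, 0)
  else ifelse(z > 0, z, cfg$leaky_alpha * z)
}
act_grad <- function(z, cfg) {
  if (cfg$activation == "relu") (z > 0) * 1
  else ifelse(z > 0, 1, cfg$leaky_alpha)
}

# normalize rows (layer norm) or columns (batch norm); returns value and
# cache for the backward pass
norm_forward <- function(z, axis) {
  if (axis == "row") {
    mu <- rowMeans(z); zc <- z - mu
    sd <- sqrt(rowMeans(zc^2) + 1e-5)
    list(y = zc / sd, zc = zc, sd = sd, axis = axis)
  } else {
    mu <- colMeans(z); zc <- sweep(z, 2, mu)
    sd <- sqrt(colMeans(zc^2) + 1e-5)
    list(y = sweep(zc, 2, sd, "/"), zc = zc, sd = sd, axis = axis,
         mu = mu)
  }
}
norm_backward <- function(dy, cache) {
  y <- if (cache$axis == "row") cache$zc / cache$sd
       else sweep(cache$zc, 2, cache$sd, "/")
  if (cache$axis == "row") {
    (dy - rowMeans(dy) - y * rowMeans(dy * y)) / cache$sd
  } else {
    t1 <- sweep(dy, 2, colMeans(dy))
    sweep(t1 - sweep(y, 2, colMeans(dy * y), "*"), 2, cache$sd, "/")
  }
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_head <- function(z, loss) {
  switch(loss,
         mse = z,
         softmax_ce = softmax_rows(z),
         bce = 1 / (1 + exp(-z)))
}

mlp_loss_value <- function(P, Y, loss) {
  switch(loss,
         mse = mean((P - Y)^2),
         softmax_ce = -mean(rowSums(Y * log(pmax(P, 1e-12)))),
         bce = -mean(Y * log(pmax(P, 1e-12)) +
                       (1 - Y) * log(pmax(1 - P, 1e-12))))
}

# forward pass; train=TRUE samples dropout masks (and uses batch stats)
mlp_forward_full <- function(net, X, train = FALSE, mc_dropout = FALSE) {
  cfg <- net$config
  L <- length(net$W)
  A <- X
  caches <- vector("list", L)
  use_dropout <- (train || mc_dropout) && cfg$dropout > 0
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    nc <- NULL
    if (l < L) {
      if (cfg$layer_norm) {
        nc <- norm_forward(Z, "row"); Z <- nc$y
      } else if (cfg$batch_norm) {
        if (train) {
          nc <- norm_forward(Z, "col"); Z <- nc$y
          net$bn_stats[[l]] <- list(mu = nc$mu, sd = nc$sd)
        } else {
          st <- net$bn_stats[[l]]
          if (!is.null(st)) {
            Z <- sweep(sweep(Z, 2, st$mu), 2, st$sd, "/")
          }
        }
      }
      H <- act_fun(Z, cfg)
      mask <- NULL
      if (use_dropout) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - cfg$dropout),
                       nrow(H)) / (1 - cfg$dropout)
        H <- H * mask
      }
      caches[[l]] <- list(A_prev = A, Z = Z, mask = mask, norm = nc)
      A <- H
    } else {
      caches[[l]] <- list(A_prev = A, Z = Z)
      A <- Z
    }
  }
  list(out = A, caches = caches, net = net)
}

mlp_backward <- function(net, fw, P, Y) {
  cfg <- net$config
  L <- length(net$W)
  n <- nrow(Y)
  dZ <- switch(net$loss,
               mse = 2 * (P - Y) / (n * ncol(Y)),
               softmax_ce = (P - Y) / n,
               bce = (P - Y) / (n * ncol(Y)))
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in seq(L, 1)) {
    cache <- fw$caches[[l]]
    gW[[l]] <- crossprod(cache$A_prev, dZ) + cfg$l2 * net$W[[l]]
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- dZ %*% t(net$W[[l]])
      prev <- fw$caches[[l - 1]]
      if (!is.null(prev$mask)) dA <- dA * prev$mask
      dZ <- dA * act_grad(prev$Z, cfg)
      if (!is.null(prev$norm)) dZ <- norm_backward(dZ, prev$norm)
    }
  }
  list(W = gW, b = gb)
}

#' Train a feed-forward network
#'
#' @param X numeric matrix of inputs (rows = examples).
#' @param Y numeric matrix of targets (regression values, soft class
#'   memberships, or multi-label indicators).
#' @param config [mlp_config()].
#' @param loss `"mse"`, `"softmax_ce"` (softmax + cross-entropy against
#'   soft targets) or `"bce"` (per-class sigmoid).
#' @param seed integer seed controlling the split, initialization and
#'   dropout masks.
#' @param init optional `mint_mlp` to initialize from (fine-tuning);
#'   architecture must match.
#' @return object of class `mint_mlp` with weights, input-normalization
#'   statistics and the training history.
#' @export
mlp_train <- function(X, Y, config = mlp_config(),
                      loss = c("mse", "softmax_ce", "bce"), seed = 1L,
                      init = NULL) {
  loss <- match.arg(loss)
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  if (loss == "mse" && stats::sd(Y) == 0) {
    warning("degenerate_target: all training targets are identical")
  }
  with_seed(seed, {
    # input normalization statistics from the full training table
    if (config$input_norm) {
      mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
      sd[sd == 0 | !is.finite(sd)] <- 1
    } else {
      mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
    }
    Xn <- sweep(sweep(X, 2, mu), 2, sd, "/")
    # 20% validation split for early stopping
    n_val <- max(1L, floor(config$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- Xn[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xva <- Xn[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

    L <- config$n_layers
    sizes <- c(ncol(X), rep(config$hidden, L - 1), ncol(Y))
    if (!is.null(init)) {
      W <- lapply(init$W, identity); b <- lapply(init$b, identity)
    } else {
      W <- vector("list", L); b <- vector("list", L)
      for (l in seq_len(L)) {
        W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1]) *
                           sqrt(2 / sizes[l]), sizes[l], sizes[l + 1])
        b[[l]] <- rep(0, sizes[l + 1])
      }
    }
    net <- structure(list(W = W, b = b, config = config, loss = loss,
                          norm = list(mu = mu, sd = sd),
                          bn_stats = vector("list", L)),
                     class = "mint_mlp")

    adam <- list(mW = lapply(W, function(w) w * 0),
                 vW = lapply(W, function(w) w * 0),
                 mb = lapply(b, function(x) x * 0),
                 vb = lapply(b, function(x) x * 0), t = 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

    eval_val <- function(net) {
      fw <- mlp_forward_full(net, Xva, train = FALSE)
      mlp_loss_value(mlp_head(fw$out, loss), Yva, loss)
    }
    best <- list(W = lapply(net$W, identity), b = lapply(net$b, identity),
                 bn = net$bn_stats, val = eval_val(net), epoch = 0L)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    wait <- 0L
    bs <- config$batch_size
    for (epoch in seq_len(config$max_epochs)) {
      batches <- if (is.null(bs) || bs >= length(tr_idx)) {
        list(seq_len(nrow(Xtr)))
      } else {
        split(sample.int(nrow(Xtr)),
              ceiling(seq_len(nrow(Xtr)) / bs))
      }
      tr_loss <- 0
      for (bi in batches) {
        Xb <- Xtr[bi, , drop = FALSE]; Yb <- Ytr[bi, , drop = FALSE]
        fw <- mlp_forward_full(net, Xb, train = TRUE)
        net$bn_stats <- fw$net$bn_stats
        P <- mlp_head(fw$out, loss)
        tr_loss <- tr_loss + mlp_loss_value(P, Yb, loss) * length(bi)
        g <- mlp_backward(net, fw, P, Yb)
        adam$t <- adam$t + 1
        bc1 <- 1 - beta1^adam$t; bc2 <- 1 - beta2^adam$t
        for (l in seq_len(L)) {
          adam$mW[[l]] <- beta1 * adam$mW[[l]] + (1 - beta1) * g$W[[l]]
          adam$vW[[l]] <- beta2 * adam$vW[[l]] + (1 - beta2) * g$W[[l]]^2
          adam$mb[[l]] <- beta1 * adam$mb[[l]] + (1 - beta1) * g$b[[l]]
          adam$vb[[l]] <- beta2 * adam$vb[[l]] + (1 - beta2) * g$b[[l]]^2
          net$W[[l]] <- net$W[[l]] - config$lr *
            (adam$mW[[l]] / bc1) / (sqrt(adam$vW[[l]] / bc2) + eps)
          net$b[[l]] <- net$b[[l]] - config$lr *
            (adam$mb[[l]] / bc1) / (sqrt(adam$vb[[l]] / bc2) + eps)
          if (config$weight_decay > 0) {
            net$W[[l]] <- net$W[[l]] * (1 - config$lr * config$weight_decay)
          }
        }
      }
      val <- eval_val(net)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss / nrow(Xtr), val_loss = val))
      if (val < best$val - 1e-9) {
        best <- list(W = lapply(net$W, identity),
                     b = lapply(net$b, identity),
                     bn = net$bn_stats, val = val, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    net$W <- best$W; net$b <- best$b; net$bn_stats <- best$bn
    net$history <- history
    net$best_epoch <- best$epoch
    net$val_loss <- best$val
    net
  })
}

#' Forward pass through a trained network
#'
#' @param net `mint_mlp`.
#' @param X input matrix (raw scale; normalization is applied
#'   internally).
#' @param mc_dropout sample dropout masks at inference (one stochastic
#'   pass); draws from the R RNG.
#' @return output matrix after the head transform (linear, softmax or
#'   sigmoid).
#' @export
mlp_predict <- function(net, X, mc_dropout = FALSE) {
  X <- as.matrix(X)
  Xn <- sweep(sweep(X, 2, net$norm$mu), 2, net$norm$sd, "/")
  fw <- mlp_forward_full(net, Xn, train = FALSE, mc_dropout = mc_dropout)
  mlp_head(fw$out, net$loss)
}
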