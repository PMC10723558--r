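# Nutrient-density prediction: category-weighted-mean baseline (FCWM),
# global five-layer regressor, per-category fine-tuned ensemble, and
# MC-dropout uncertainty intervals.

#' Per-category true-mean statistics
#'
#' @param scores numeric nutrient-density scores.
#' @param hard_labels integer category labels (1..k; 0 = noise is
#'   dropped).
#' @param n_categories total category count (defaults to max label).
#' @return object of class `mint_category_stats` with `true_mean` and
#'   `count` per category (categories with no items get the global
#'   mean).
#' @export
category_stats <- function(scores, hard_labels,
                           n_categories = max(hard_labels)) {
  keep <- hard_labels > 0
  scores <- scores[keep]; hard_labels <- hard_labels[keep]
  tm <- rep(mean(scores), n_categories)
  cnt <- integer(n_categories)
  for (c in seq_len(n_categories)) {
    idx <- hard_labels == c
    cnt[c] <- sum(idx)
    if (cnt[c] > 0) tm[c] <- mean(scores[idx])
  }
  structure(list(true_mean = tm, count = cnt,
                 n_categories = n_categories),
            class = "mint_category_stats")
}

#' Food-category weighted mean (FCWM) baseline
#'
#' The closed-form baseline `sum_i p_i * TM_i`: category confidences
#' times per-category true-mean scores.
#'
#' @param category_probs probability vector over categories, or a
#'   matrix with one row per item (rows must sum to 1 within 1e-6).
#' @param stats [category_stats()] output.
#' @return numeric score(s).
#' @export
#' @examples
#' st <- structure(list(true_mean = c(1, 0.5), count = c(10L, 10L),
#'                      n_categories = 2L), class = "mint_category_stats")
#' fcwm_predict(c(0.7, 0.3), st)  # 0.85
fcwm_predict <- function(category_probs, stats) {
  P <- if (is.null(dim(category_probs))) {
    matrix(category_probs, nrow = 1)
  } else as.matrix(category_probs)
  if (ncol(P) != stats$n_categories) {
    stop("length_mismatch: ", ncol(P), " probabilities vs ",
         stats$n_categories, " categories", call. = FALSE)
  }
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  out <- as.numeric(P %*% stats$true_mean)
  if (is.null(dim(category_probs))) out[1] else out
}

#' Train the global nutrient-density regressor
#'
#' Five-layer network with a linear output, trained by minimizing mean
#' squared error against the item scores, with early stopping on a 20%
#' validation split.
#'
#' @param name_vectors embedding matrix of item names.
#' @param scores numeric RRR or RRRmacro targets.
#' @param config [mlp_config()].
#' @param variant `"rrr_macro"` or `"rrr"` (metadata only).
#' @param seed integer seed.
#' @return object of class `mint_regressor`.
#' @export
train_global_regressor <- function(name_vectors, scores,
                                   config = mlp_config(),
                                   variant = c("rrr_macro", "rrr"),
                                   seed = 1L) {
  variant <- match.arg(variant)
  X <- as.matrix(name_vectors)
  stopifnot(all(is.finite(scores)))
  if (nrow(X) < 50) {
    stop("too_few_points: need >= 50 training items", call. = FALSE)
  }
  net <- mlp_train(X, matrix(scores, ncol = 1), config = config,
                   loss = "mse", seed = seed)
  structure(list(net = net, variant = variant, input_dim = ncol(X),
                 config = config),
            class = "mint_regressor")
}

#' Predict scores with a regressor (deterministic pass)
#'
#' @param regressor `mint_regressor` or a fine-tuned copy.
#' @param name_vectors embedding matrix.
#' @param mc_dropout sample one stochastic dropout pass.
#' @return numeric predictions.
#' @export
predict_scores <- function(regressor, name_vectors, mc_dropout = FALSE) {
  as.numeric(mlp_predict(regressor$net, as.matrix(name_vectors),
                         mc_dropout = mc_dropout))
}

#' Fine-tune per-category copies of the global regressor
#'
#' Splits the training data by hard pseudo-label and fine-tunes one
#' copy of the base model per category (all layers, same learning rate,
#' decoupled weight decay 0.001), with early stopping on a per-category
#' validation split; the initial (base) weights are kept whenever
#' fine-tuning does not improve validation loss. Categories with fewer
#' than `min_finetune_items` items fall back to the base model.
#'
#' @param base [train_global_regressor()] output.
#' @param name_vectors,scores training data (same rows as
#'   `hard_labels`).
#' @param hard_labels integer pseudo-label per item (0 = noise,
#'   excluded).
#' @param config optional [mlp_config()] for fine-tuning; defaults to
#'   the base configuration with `weight_decay = 0.001`.
#' @param min_finetune_items smallest category trained (default 20).
#' @param epochs optional cap on fine-tuning epochs (0 = no
#'   fine-tuning, every copy equals the base).
#' @param seed integer seed.
#' @return object of class `mint_ensemble`.
#' @export
finetune_per_category <- function(base, name_vectors, scores, hard_labels,
                                  config = NULL, min_finetune_items = 20,
                                  epochs = NULL, seed = 1L) {
  X <- as.matrix(name_vectors)
  n_cat <- max(hard_labels)
  if (is.null(config)) {
    config <- base$config
    config$weight_decay <- 0.001
  }
  if (!is.null(epochs)) config$max_epochs <- epochs
  models <- vector("list", n_cat)
  fallback <- logical(n_cat)
  for (c in seq_len(n_cat)) {
    idx <- which(hard_labels == c)
    if (length(idx) < min_finetune_items || identical(config$max_epochs, 0)) {
      models[[c]] <- base
      fallback[c] <- TRUE
      next
    }
    net <- mlp_train(X[idx, , drop = FALSE],
                     matrix(scores[idx], ncol = 1), config = config,
                     loss = "mse", seed = stage_seed(seed, c),
                     init = base$net)
    models[[c]] <- structure(list(net = net, variant = base$variant,
                                  input_dim = base$input_dim,
                                  config = config),
                             class = "mint_regressor")
  }
  structure(list(base = base, models = models, n_categories = n_cat,
                 fallback = fallback, variant = base$variant,
                 min_finetune_items = min_finetune_items),
            class = "mint_ensemble")
}

#' Route items through the fine-tuned ensemble (deterministic pass)
#'
#' @param ensemble [finetune_per_category()] output.
#' @param name_vectors embedding matrix.
#' @param category_probs probability matrix from [predict_category()].
#' @param routing `"hard"` routes each item to its argmax category's
#'   model; `"soft"` mixes all per-category predictions by the
#'   category confidences.
#' @return numeric predictions.
#' @export
predict_ensemble <- function(ensemble, name_vectors, category_probs,
                             routing = c("hard", "soft")) {
  routing <- match.arg(routing)
  X <- as.matrix(name_vectors)
  P <- as.matrix(category_probs)
  per_cat <- vapply(seq_len(ensemble$n_categories), function(c)
    predict_scores(ensemble$models[[c]], X), numeric(nrow(X)))
  per_cat <- matrix(per_cat, nrow = nrow(X))
  if (routing == "soft") {
    rowSums(per_cat * P)
  } else {
    hard <- apply(P, 1, arg_max)
    per_cat[cbind(seq_len(nrow(X)), hard)]
  }
}

#' Predict nutrient density with MC-dropout uncertainty
#'
#' Embeds each name, predicts its category, routes it to that
#' category's fine-tuned model, and runs `n_mc` stochastic forward
#' passes with dropout active. The point estimate is the mean of the
#' passes; the interval is the 2.5/97.5 percentile band (or
#' mean +/- 1.96 SD with `ci_method = "normal"`). The interval is
#' widened to contain the point estimate if the percentile band misses
#' it (possible only for strongly skewed pass distributions).
#'
#' @param ensemble [finetune_per_category()] output.
#' @param predictor [train_category_predictor()] output.
#' @param model [train_embedding_model()] output.
#' @param names character vector of item names (non-empty).
#' @param n_mc MC-dropout iterations (default 100).
#' @param level interval coverage (default 0.95).
#' @param ci_method `"percentile"` or `"normal"`.
#' @param routing `"hard"` (default) or `"soft"`, see
#'   [predict_ensemble()].
#' @param seed integer seed for the dropout draws.
#' @return data.frame: `name, predicted_category, category_confidence,
#'   score, ci_low, ci_high` (class `mint_prediction`).
#' @export
predict_with_uncertainty <- function(ensemble, predictor, model, names,
                                     n_mc = 100, level = 0.95,
                                     ci_method = c("percentile", "normal"),
                                     routing = c("hard", "soft"),
                                     seed = 1L) {
  ci_method <- match.arg(ci_method)
  routing <- match.arg(routing)
  stopifnot(n_mc >= 1)
  if (any(is.na(names) | trimws(names) == "")) {
    stop("empty_name: item names must be non-empty", call. = FALSE)
  }
  X <- embed_name(model, names)
  P <- predict_category(predictor, X)
  hard <- apply(P, 1, arg_max)
  conf <- P[cbind(seq_len(nrow(P)), hard)]
  draws <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      if (routing == "soft") {
        per_cat <- vapply(seq_len(ensemble$n_categories), function(c)
          predict_scores(ensemble$models[[c]], X, mc_dropout = TRUE),
          numeric(nrow(X)))
        rowSums(matrix(per_cat, nrow = nrow(X)) * P)
      } else {
        out <- numeric(nrow(X))
        for (c in unique(hard)) {
          idx <- hard == c
          out[idx] <- predict_scores(ensemble$models[[c]],
                                     X[idx, , drop = FALSE],
                                     mc_dropout = TRUE)
        }
        out
      }
    }, numeric(nrow(X)))
  })
  draws <- matrix(draws, nrow = nrow(X))
  point <- rowMeans(draws)
  if (ci_method == "normal") {
    s <- apply(draws, 1, stats::sd)
    if (n_mc == 1) s <- rep(0, nrow(X))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- point - z * s; hi <- point + z * s
  } else {
    a <- (1 - level) / 2
    lo <- apply(draws, 1, stats::quantile, probs = a, names = FALSE)
    hi <- apply(draws, 1, stats::quantile, probs = 1 - a, names = FALSE)
  }
  lo <- pmin(lo, point); hi <- pmax(hi, point)
  out <- data.frame(name = names, predicted_category = hard,
                    category_confidence = conf, score = point,
                    ci_low = lo, ci_high = hi,
                    stringsAsFactors = FALSE)
  attr(out, "variant") <- ensemble$variant
  attr(out, "n_mc") <- n_mc
  class(out) <- c("mint_prediction", "data.frame")
  out
}
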