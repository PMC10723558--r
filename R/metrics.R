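# Regression metrics and the ablation harness comparing the FCWM
# baseline, the global regressor, and the fine-tuned ensemble.

#' Regression metrics (R-squared, RMSE, MAE, match rate)
#'
#' `R2 = 1 - SS_res / SS_tot` (negative values mean the predictor is
#' worse than guessing the mean of the truth). `match_rate` is the
#' fraction of items actually scored (non-NA predictions); metrics are
#' computed over scored items only.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return list of class `mint_metrics`: `r_squared, rmse, mae,
#'   match_rate, n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop("length_mismatch: need equal non-zero lengths", call. = FALSE)
  }
  ok <- !is.na(y_pred) & !is.na(y_true)
  match_rate <- mean(!is.na(y_pred))
  y <- y_true[ok]; p <- y_pred[ok]
  if (length(y) == 0) stop("length_mismatch: no scored items", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("zero_variance: R-squared undefined for constant y_true",
         call. = FALSE)
  }
  structure(list(
    r_squared = 1 - sum((y - p)^2) / ss_tot,
    rmse = sqrt(mean((y - p)^2)),
    mae = mean(abs(y - p)),
    match_rate = match_rate,
    n = length(y)
  ), class = "mint_metrics")
}

#' @export
print.mint_metrics <- function(x, ...) {
  cat(sprintf("R^2 = %.4f  RMSE = %.4f  MAE = %.4f  matched = %.0f%% (n = %d)\n",
              x$r_squared, x$rmse, x$mae, 100 * x$match_rate, x$n))
  invisible(x)
}

# stratified train/test split by a grouping factor
stratified_split <- function(groups, test_frac = 0.2, seed = 1L) {
  with_seed(seed, {
    test <- unlist(lapply(split(seq_along(groups), groups), function(idx) {
      n_test <- max(1L, round(test_frac * length(idx)))
      sample(idx, n_test)
    }))
    list(train = setdiff(seq_along(groups), test), test = sort(test))
  })
}

#' Ablation study over prediction heads
#'
#' Reproduces the model-comparison protocol at synthetic scale: the
#' embedding model and pseudo-labels are fitted once (they are fixed
#' upstream artifacts), then for each seed the items are split 80/20
#' (stratified by true category), the category predictor and prediction
#' heads are trained on the training fold, and the held-out fold is
#' scored. Heads: `"fcwm"` (category-weighted true means), `"global"`
#' (single regressor), `"ensemble"` (per-category fine-tuned copies
#' routed by predicted category).
#'
#' @param corpus [generate_food_items()] output.
#' @param heads character subset of `c("fcwm", "global", "ensemble")`.
#' @param n_seeds number of replicate seeds.
#' @param variant `"rrr_macro"` or `"rrr"`.
#' @param embed_params list passed to [train_embedding_model()].
#' @param mlp list passed to [mlp_config()].
#' @param reducer_params,clusterer_params passed to
#'   [fit_pseudo_labels()].
#' @param min_finetune_items passed to [finetune_per_category()].
#' @param seed base seed; replicate s uses `seed + s`.
#' @return list of class `mint_ablation`: `runs` (per seed x head
#'   metrics data.frame), `summary` (mean and SD per head), and the
#'   shared artifacts.
#' @export
run_ablation <- function(corpus,
                         heads = c("fcwm", "global", "ensemble"),
                         n_seeds = 5, variant = c("rrr_macro", "rrr"),
                         embed_params = list(dim = 50, epochs = 8),
                         mlp = list(hidden = 64, max_epochs = 300),
                         reducer_params = list(),
                         clusterer_params = list(),
                         min_finetune_items = 20, seed = 1L) {
  variant <- match.arg(variant)
  heads <- match.arg(heads, several.ok = TRUE)
  if (length(heads) < 1) stop("need at least one head", call. = FALSE)
  items <- corpus$items
  scores <- if (variant == "rrr_macro") items$rrr_macro else items$rrr

  docs <- generate_recipe_corpus(corpus)
  emb <- do.call(train_embedding_model,
                 c(list(corpus = docs, seed = stage_seed(seed, 1)),
                   embed_params))
  name_vecs <- embed_name(emb, items$name)
  enc <- context_encoder(emb)
  sentences <- mapply(function(nm, ing) {
    build_context_sentence(nm, strsplit(ing, ";", fixed = TRUE)[[1]])
  }, items$name, items$ingredients, USE.NAMES = FALSE)
  ctx <- embed_context(enc, sentences)
  pl <- fit_pseudo_labels(ctx, reducer_params, clusterer_params,
                          seed = stage_seed(seed, 2))
  cfg <- do.call(mlp_config, mlp)

  runs <- list()
  for (s in seq_len(n_seeds)) {
    rs <- stage_seed(seed, 10 + s)
    split <- stratified_split(items$true_category, 0.2, seed = rs)
    tr <- split$train; te <- split$test
    pl_tr <- list(membership = pl$membership[tr, , drop = FALSE],
                  is_noise = pl$is_noise[tr])
    pred <- train_category_predictor(name_vecs[tr, , drop = FALSE],
                                     pl_tr, config = cfg, seed = rs)
    P_te <- predict_category(pred, name_vecs[te, , drop = FALSE])
    for (h in heads) {
      y_hat <- switch(
        h,
        fcwm = {
          st <- category_stats(scores[tr], pl$hard_label[tr] *
                                 (!pl$is_noise[tr]),
                               n_categories = pl$n_clusters)
          fcwm_predict(P_te, st)
        },
        global = {
          reg <- train_global_regressor(name_vecs[tr, , drop = FALSE],
                                        scores[tr], config = cfg,
                                        variant = variant, seed = rs)
          predict_scores(reg, name_vecs[te, , drop = FALSE])
        },
        ensemble = {
          reg <- train_global_regressor(name_vecs[tr, , drop = FALSE],
                                        scores[tr], config = cfg,
                                        variant = variant, seed = rs)
          labs <- pl$hard_label[tr] * (!pl$is_noise[tr])
          ens <- finetune_per_category(reg, name_vecs[tr, , drop = FALSE],
                                       scores[tr], labs,
                                       min_finetune_items = min_finetune_items,
                                       seed = rs)
          predict_ensemble(ens, name_vecs[te, , drop = FALSE], P_te)
        })
      m <- regression_metrics(scores[te], y_hat)
      runs[[length(runs) + 1]] <- data.frame(
        head = h, seed = s, r_squared = m$r_squared, rmse = m$rmse,
        mae = m$mae, n = m$n, stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$head), function(d) {
    data.frame(head = d$head[1],
               r_squared_mean = mean(d$r_squared),
               r_squared_sd = if (nrow(d) > 1) stats::sd(d$r_squared) else 0,
               rmse_mean = mean(d$rmse),
               rmse_sd = if (nrow(d) > 1) stats::sd(d$rmse) else 0,
               mae_mean = mean(d$mae),
               mae_sd = if (nrow(d) > 1) stats::sd(d$mae) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, variant = variant,
                 pseudo_labels = pl, embedding = emb,
                 name_vectors = name_vecs),
            class = "mint_ablation")
}

#' @export
print.mint_ablation <- function(x, ...) {
  cat("Ablation (", x$variant, ", ",
      length(unique(x$runs$seed)), " seeds):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
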