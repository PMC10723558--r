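# The synthetic benchmark world used by the test suite and acceptance
# report, and an in-memory end-to-end trainer. Scale-downs relative to
# the package defaults (embedding dim 50 instead of 300, hidden width
# 64 instead of 256, max 300 epochs) keep the benchmark inside a
# single-CPU desk budget; the statistical structure of the world is
# fixed independently of any test outcome.

#' Benchmark training parameters
#'
#' @return list with `embed_params` and `mlp` lists.
#' @export
benchmark_params <- function() {
  list(embed_params = list(dim = 50, epochs = 8),
       mlp = list(hidden = 64, max_epochs = 300, lr = 1e-2,
                  dropout = 0.1))
}

#' Default synthetic benchmark corpus
#'
#' 4 categories x 500 items with category-mean RRRmacro planted at
#' {0.3, 0.7, 1.1, 1.5} and nutrient CV 0.15 (the [synthetic_config()]
#' defaults).
#'
#' @param seed integer seed.
#' @param items_per_category override for smaller test fixtures.
#' @return `mint_synthetic_corpus`.
#' @export
benchmark_corpus <- function(seed = 1L, items_per_category = 500) {
  generate_food_items(synthetic_config(items_per_category = items_per_category,
                                       seed = seed))
}

#' Train the full model stack in memory
#'
#' Convenience wrapper over the individual stages: embeds the corpus,
#' fits pseudo-labels, trains the category predictor, the global
#' regressor and the fine-tuned ensemble on a stratified 80% training
#' fold, and returns everything with the held-out fold indices.
#'
#' @param corpus [generate_food_items()] output.
#' @param variant `"rrr_macro"` or `"rrr"`.
#' @param embed_params,mlp parameter lists (default [benchmark_params()]).
#' @param test_frac held-out fraction (0 disables the split).
#' @param min_finetune_items passed to [finetune_per_category()].
#' @param seed integer seed.
#' @return list of class `mint_fit` with the trained components,
#'   `train`/`test` row indices and the per-item `scores`.
#' @export
fit_mint <- function(corpus, variant = c("rrr_macro", "rrr"),
                     embed_params = benchmark_params()$embed_params,
                     mlp = benchmark_params()$mlp,
                     test_frac = 0.2, min_finetune_items = 20,
                     seed = 1L) {
  variant <- match.arg(variant)
  items <- corpus$items
  scores <- if (variant == "rrr_macro") items$rrr_macro else items$rrr
  docs <- generate_recipe_corpus(corpus)
  emb <- do.call(train_embedding_model,
                 c(list(corpus = docs, seed = stage_seed(seed, 1)),
                   embed_params))
  name_vecs <- embed_name(emb, items$name)
  sentences <- mapply(function(nm, ing) {
    build_context_sentence(nm, strsplit(ing, ";", fixed = TRUE)[[1]])
  }, items$name, items$ingredients, USE.NAMES = FALSE)
  ctx <- embed_context(context_encoder(emb), sentences)
  pl <- fit_pseudo_labels(ctx, seed = stage_seed(seed, 2))
  if (test_frac > 0) {
    split <- stratified_split(items$true_category, test_frac,
                              seed = stage_seed(seed, 3))
  } else {
    split <- list(train = seq_len(nrow(items)), test = integer(0))
  }
  tr <- split$train
  cfg <- do.call(mlp_config, mlp)
  pl_tr <- list(membership = pl$membership[tr, , drop = FALSE],
                is_noise = pl$is_noise[tr])
  predictor <- train_category_predictor(name_vecs[tr, , drop = FALSE],
                                        pl_tr, config = cfg,
                                        seed = stage_seed(seed, 4))
  regressor <- train_global_regressor(name_vecs[tr, , drop = FALSE],
                                      scores[tr], config = cfg,
                                      variant = variant,
                                      seed = stage_seed(seed, 5))
  labs <- pl$hard_label * (!pl$is_noise)
  ensemble <- finetune_per_category(regressor,
                                    name_vecs[tr, , drop = FALSE],
                                    scores[tr], labs[tr],
                                    min_finetune_items = min_finetune_items,
                                    seed = stage_seed(seed, 6))
  structure(list(
    corpus = corpus, embedding = emb, name_vectors = name_vecs,
    pseudo_labels = pl, predictor = predictor, regressor = regressor,
    ensemble = ensemble, scores = scores, variant = variant,
    train = split$train, test = split$test, mlp_config = cfg,
    seed = seed
  ), class = "mint_fit")
}
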