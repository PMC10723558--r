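# Shared fixtures, memoized across test files within the session (the
# benchmark fit is expensive; several files and the acceptance suite
# reuse it). All fixtures are generated in code under fixed seeds.

if (!exists(".mintr_cache", envir = globalenv())) {
  assign(".mintr_cache", new.env(parent = emptyenv()), envir = globalenv())
}

cache_get <- function(key, expr) {
  cache <- get(".mintr_cache", envir = globalenv())
  if (!exists(key, envir = cache)) assign(key, force(expr), envir = cache)
  get(key, envir = cache)
}

# full benchmark world: 4 categories x 500 items, seed 1
bench_corpus <- function() cache_get("bench_corpus", benchmark_corpus(seed = 1))

# trained stack on the benchmark corpus (80/20 split)
bench_fit <- function() cache_get("bench_fit", fit_mint(bench_corpus(), seed = 1))

# small corpus + embedding model for cheap unit tests
small_corpus <- function() {
  cache_get("small_corpus",
            generate_food_items(synthetic_config(items_per_category = 60,
                                                 seed = 7)))
}

small_embedding <- function() {
  cache_get("small_embedding", {
    docs <- generate_recipe_corpus(small_corpus())
    train_embedding_model(docs, dim = 30, epochs = 5, seed = 7)
  })
}

# context-sentence embeddings of the small corpus
small_context <- function() {
  cache_get("small_context", {
    corpus <- small_corpus()
    sent <- mapply(function(n, i) {
      build_context_sentence(n, strsplit(i, ";", fixed = TRUE)[[1]])
    }, corpus$items$name, corpus$items$ingredients, USE.NAMES = FALSE)
    embed_context(context_encoder(small_embedding()), sent)
  })
}

# a complete nutrient profile at exactly the daily value for everything
profile_at_dv <- function() nutrient_profile(as.list(daily_values()))

# random complete profile (uniform amounts up to 2x DV)
random_profile <- function() {
  dv <- daily_values()
  nutrient_profile(as.list(stats::runif(length(dv), 0, 2) * dv))
}

# independent direct transcription of the two index definitions:
# mean %DV of the numerator set over mean %DV of the restricted set
# independent transcription of the histogram outlier ranking
oracle_hbos <- function(scores, contamination) {
  n <- length(scores)
  n_bins <- max(1L, as.integer(round(sqrt(n))))
  rng <- range(scores)
  if (rng[2] == rng[1]) return(integer(0))
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((scores - rng[1]) / width) + 1L, n_bins)
  counts <- table(factor(bin, levels = 1:n_bins))
  score <- -log(as.numeric(counts[bin]) / (n * width))
  k <- floor(contamination * n)
  if (k == 0) return(integer(0))
  sort(order(-score, seq_len(n))[seq_len(k)])
}

oracle_rrr <- function(profile, macro = FALSE) {
  dv <- c(protein = 50, fiber = 28, vitamin_a = 900, vitamin_c = 90,
          calcium = 1300, iron = 18, calories = 2000, total_sugar = 50,
          cholesterol = 300, saturated_fat = 20, sodium = 2300)
  pdv <- 100 * unclass(profile)[names(dv)] / dv
  num_keys <- if (macro) c("protein", "fiber") else
    c("protein", "fiber", "vitamin_a", "vitamin_c", "calcium", "iron")
  den_keys <- c("calories", "total_sugar", "cholesterol",
                "saturated_fat", "sodium")
  mean(pdv[num_keys]) / mean(pdv[den_keys])
}
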