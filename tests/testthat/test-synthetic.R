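test_that("generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(items_per_category = 30, seed = 42)
  a <- generate_food_items(cfg)
  b <- generate_food_items(cfg)
  expect_identical(a$items, b$items)
  c_ <- generate_food_items(synthetic_config(items_per_category = 30,
                                             seed = 43))
  expect_false(identical(a$items$name, c_$items$name))
  expect_identical(dim(a$items), dim(c_$items))
})

test_that("zero noise collapses items to the category mean profile", {
  cfg <- synthetic_config(items_per_category = 5, nutrient_cv = 0,
                          word_effect_sd = 0, seed = 1)
  out <- generate_food_items(cfg)
  for (c_ in 1:4) {
    mu <- unclass(cfg$nutrient_means[[c_]])
    rows <- out$items[out$items$true_category == c_, ]
    expect_equal(unname(rows$protein_g), rep(mu[["protein"]], 5))
    expect_equal(unname(rows$sodium_mg), rep(mu[["sodium"]], 5))
    expect_equal(rows$rrr_macro, rep(cfg$target_rrr_macro[c_], 5),
                 tolerance = 1e-10)
  }
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_categories = 1), "n_categories")
  expect_error(synthetic_config(vocab = list(character(0), "a")),
               "empty_vocabulary")
  expect_error(synthetic_config(name_length_range = c(0, 2)),
               "name_length_range")
})

test_that("per-category mean RRRmacro recovers the planted values", {
  items <- bench_corpus()$items   # 500 items per category, CV 0.15
  targets <- c(0.3, 0.7, 1.1, 1.5)
  for (c_ in 1:4) {
    x <- items$rrr_macro[items$true_category == c_]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - targets[c_]), 3 * se + 0.02)
  }
})

test_that("recipe corpus has one document per item with name and ingredients", {
  corpus <- small_corpus()
  docs <- generate_recipe_corpus(corpus)
  expect_length(docs, nrow(corpus$items))
  expect_gt(attr(docs, "n_tokens"), 0)
  bare <- generate_recipe_corpus(corpus, include_filler = FALSE)
  i <- 1L
  expect_identical(
    bare[i],
    paste(corpus$items$name[i],
          gsub(";", " ", corpus$items$ingredients[i], fixed = TRUE)))
  # every vocabulary word appears somewhere once items outnumber vocab
  toks <- unique(unlist(tokenize_text(docs)))
  expect_true(all(unlist(corpus$config$vocab) %in% toks))
})

test_that("restaurant menus follow their category mixes", {
  corpus <- small_corpus()
  one <- generate_restaurants(corpus, n_restaurants = 1,
                              menu_size_range = c(1, 1), seed = 3)
  expect_identical(nrow(one), 1L)
  hot <- generate_restaurants(corpus, n_restaurants = 3,
                              menu_size_range = c(5, 10),
                              category_mix = c(0, 0, 1, 0), seed = 3)
  expect_true(all(hot$true_category == 3))
  expect_error(generate_restaurants(corpus, menu_size_range = c(0, 5)),
               "invalid_menu_size")
  expect_error(generate_restaurants(corpus, n_restaurants = 2,
                                    category_mix = c(0.5, 0.2, 0.2, 0.2),
                                    seed = 1),
               "invalid_weights")
})

test_that("mix-implied expected score tracks true menu-median RRRmacro", {
  corpus <- bench_corpus()
  # 20 restaurants whose mixes sweep a peak across the four categories
  centers <- seq(1, 4, length.out = 20)
  mix <- t(vapply(centers, function(m) {
    w <- stats::dnorm(1:4, m, 0.7); w / sum(w)
  }, numeric(4)))
  menus <- generate_restaurants(corpus, n_restaurants = 20,
                                menu_size_range = c(15, 40),
                                category_mix = mix, seed = 9)
  cat_means <- tapply(corpus$items$rrr_macro, corpus$items$true_category,
                      mean)
  implied <- as.numeric(mix %*% cat_means)
  true_rnd <- restaurant_rnd(menus)$rnd
  expect_gte(stats::cor(implied, true_rnd, method = "spearman"), 0.9)
})

test_that("names are category-separable by a bag-of-words centroid classifier", {
  items <- bench_corpus()$items
  toks <- tokenize_text(items$name)
  vocab <- sort(unique(unlist(toks)))
  bow <- matrix(0, nrow(items), length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(toks)) bow[i, toks[[i]]] <- 1
  set.seed(5)
  te <- sample(nrow(items), 400)
  tr <- setdiff(seq_len(nrow(items)), te)
  centroids <- do.call(rbind, lapply(1:4, function(c_) {
    colMeans(bow[tr[items$true_category[tr] == c_], , drop = FALSE])
  }))
  sim <- bow[te, ] %*% t(centroids) /
    outer(sqrt(rowSums(bow[te, ]^2)), sqrt(rowSums(centroids^2)))
  pred <- apply(sim, 1, which.max)
  expect_gte(mean(pred == items$true_category[te]), 0.95)
})
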