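# Seeded synthetic generator for food items, recipe corpora and
# restaurant menus with planted category structure. It emulates the
# shape of generic-food-item databases (name + ingredient list +
# nutrient vector) at desk scale so every downstream stage is testable
# without licensed data.

shared_vocab_pool <- function() {
  c("chicken", "cheese", "special", "house", "crispy", "classic",
    "golden", "original", "signature", "deluxe")
}

default_category_vocabs <- function() {
  list(
    dessert = c("cake", "fudge", "brownie", "caramel", "vanilla",
                "chocolate", "swirl", "glazed", "frosted", "sundae",
                "cookie", "cream", "pie", "cinnamon", "roll", "donut",
                "mousse", "custard", "toffee", "praline", "sprinkle",
                "velvet", "banana", "split", "waffle", "syrup", "honey"),
    fried   = c("fried", "crunchy", "battered", "nugget", "wing", "bacon",
                "burger", "loaded", "double", "patty", "hash", "onion",
                "ring", "popcorn", "tender", "spicy", "buffalo",
                "barbecue", "smoky", "jumbo", "combo", "basket", "fries",
                "gravy", "biscuit", "corndog", "melt"),
    deli    = c("sandwich", "wrap", "club", "turkey", "ham", "hoagie",
                "panini", "toasted", "rye", "sourdough", "swiss",
                "pickle", "mustard", "deli", "stack", "grinder",
                "flatbread", "ciabatta", "pesto", "roast", "beef",
                "pepper", "jack", "bagel", "lox", "reuben", "sub"),
    salad   = c("salad", "kale", "quinoa", "spinach", "avocado", "citrus",
                "garden", "harvest", "grilled", "veggie", "sprout",
                "beet", "lentil", "chickpea", "greens", "arugula",
                "walnut", "berry", "vinaigrette", "fresh", "farm",
                "bowl", "super", "detox", "cucumber", "herb", "tofu")
  )
}

default_ingredient_pools <- function() {
  list(
    dessert = c("sugar", "butter", "flour", "cocoa", "egg", "milk",
                "frosting", "sprinkles", "caramel", "pecans",
                "marshmallow", "nutmeg", "molasses", "shortening",
                "honey", "cinnamon", "cream", "icing", "wafer",
                "gelatin", "raisins", "coconut", "almond", "jam",
                "dough"),
    fried   = c("oil", "breadcrumbs", "lard", "salt", "ketchup", "mayo",
                "bun", "beef", "pork", "batter", "paprika", "cayenne",
                "ranch", "lettuce", "tomato", "onion", "potato",
                "pickles", "cheddar", "bacon", "sausage", "grease",
                "cornmeal", "buttermilk", "seasoning"),
    deli    = c("bread", "turkey", "ham", "mustard", "mayo", "swiss",
                "provolone", "lettuce", "tomato", "onion", "pickle",
                "oregano", "vinegar", "olive", "salami", "pastrami",
                "roll", "sprouts", "hummus", "basil", "garlic",
                "pepperoni", "mozzarella", "spread", "butter"),
    salad   = c("lettuce", "kale", "spinach", "quinoa", "lemon", "olive",
                "oil", "vinegar", "tomato", "cucumber", "carrot",
                "radish", "chickpeas", "lentils", "almond", "walnut",
                "cranberry", "feta", "yogurt", "mint", "parsley",
                "cilantro", "lime", "tahini", "seeds")
  )
}

# restricted-side archetypes (amounts in DV-table units) and
# micronutrients; protein fixed, fiber solved so the mean profile's
# RRRmacro equals the planted target exactly.
default_category_archetypes <- function() {
  list(
    dessert = list(calories = 450, total_sugar = 45, cholesterol = 90,
                   saturated_fat = 9, sodium = 400, protein = 5,
                   vitamin_a = 80, vitamin_c = 2, calcium = 120,
                   iron = 1.5),
    fried   = list(calories = 800, total_sugar = 8, cholesterol = 120,
                   saturated_fat = 10, sodium = 1400, protein = 25,
                   vitamin_a = 30, vitamin_c = 5, calcium = 60,
                   iron = 2.5),
    deli    = list(calories = 600, total_sugar = 10, cholesterol = 70,
                   saturated_fat = 6, sodium = 1000, protein = 28,
                   vitamin_a = 150, vitamin_c = 15, calcium = 250,
                   iron = 3.5),
    salad   = list(calories = 350, total_sugar = 7, cholesterol = 15,
                   saturated_fat = 2.5, sodium = 500, protein = 12,
                   vitamin_a = 400, vitamin_c = 45, calcium = 180,
                   iron = 4)
  )
}

#' Build a category-mean nutrient profile with a planted RRRmacro
#'
#' Given the restricted-nutrient amounts, micronutrients and protein of
#' an archetype, solves for the fiber amount so that the profile's
#' RRRmacro equals `target` exactly.
#'
#' @param target desired RRRmacro of the mean profile.
#' @param archetype named list of amounts for the restricted nutrients,
#'   protein and the four micronutrients.
#' @return [nutrient_profile()].
#' @export
profile_for_rrr_macro <- function(target, archetype) {
  dv <- daily_values()
  restr <- restricted_nutrients()
  pdv_restr <- vapply(restr, function(k)
    100 * archetype[[k]] / dv[[k]], numeric(1))
  r_mean <- mean(pdv_restr)
  pdv_protein <- 100 * archetype$protein / dv[["protein"]]
  pdv_fiber <- 2 * target * r_mean - pdv_protein
  if (pdv_fiber < 0) {
    stop("archetype protein too high for target RRRmacro ", target,
         call. = FALSE)
  }
  nutrient_profile(c(archetype,
                     list(fiber = pdv_fiber * dv[["fiber"]] / 100)))
}

#' Synthetic-world configuration
#'
#' Describes a population of food items with latent category structure:
#' each category has a name vocabulary, an ingredient pool and a mean
#' nutrient profile whose RRRmacro is planted at a known value. Item
#' nutrient amounts are drawn log-normally around the category mean with
#' coefficient of variation `nutrient_cv`; in addition each vocabulary
#' word carries a category-specific log-scale "healthiness" effect
#' (SD `word_effect_sd`) applied to protein and fiber, so an item's
#' name is informative about its score beyond its category.
#'
#' Defaults state the benchmark world used throughout the test suite:
#' 4 categories x 500 items, planted category-mean RRRmacro
#' {0.3, 0.7, 1.1, 1.5}, `nutrient_cv = 0.15`, 30-word vocabularies with
#' overlap fraction 0.1, names of 2-4 words.
#'
#' @param n_categories number of latent categories (>= 2).
#' @param items_per_category items generated per category.
#' @param vocab list of character vectors (one per category), or `NULL`
#'   for the built-in food vocabularies.
#' @param ingredient_pools list of character vectors, or `NULL`.
#' @param nutrient_means list of [nutrient_profile()], or `NULL` to
#'   build them from the archetypes with `target_rrr_macro`.
#' @param target_rrr_macro planted category-mean RRRmacro values.
#' @param nutrient_cv coefficient of variation of the log-normal
#'   nutrient noise.
#' @param word_effect_sd SD of per-word log-scale effects on protein and
#'   fiber (0 disables name-linked variation).
#' @param ingredient_align strength of the association between an
#'   item's healthiness effect and its sampled ingredients (healthier
#'   items list healthier ingredients, giving the name-level effects a
#'   corpus footprint the embedding model can learn; 0 disables).
#' @param vocab_overlap fraction of each vocabulary replaced by words
#'   shared across categories (ambiguous names).
#' @param name_length_range integer (min, max) words per item name.
#' @param ingredients_range integer (min, max) ingredients per item.
#' @param seed integer seed; the corpus is a pure function of
#'   (config, seed).
#' @return object of class `mint_synthetic_config`.
#' @export
synthetic_config <- function(n_categories = 4, items_per_category = 500,
                             vocab = NULL, ingredient_pools = NULL,
                             nutrient_means = NULL,
                             target_rrr_macro = c(0.3, 0.7, 1.1, 1.5),
                             nutrient_cv = 0.15, word_effect_sd = 0.4,
                             ingredient_align = 10,
                             vocab_overlap = 0.1,
                             name_length_range = c(2L, 4L),
                             ingredients_range = c(3L, 6L),
                             seed = 1L) {
  if (n_categories < 2) stop("n_categories must be >= 2", call. = FALSE)
  if (items_per_category < 1) stop("items_per_category must be >= 1",
                                   call. = FALSE)
  if (is.null(vocab)) {
    base <- default_category_vocabs()
    vocab <- lapply(seq_len(n_categories), function(c) {
      if (c <= length(base)) base[[c]]
      else sprintf("food%d%s", c, letters[1:27])
    })
    names(vocab) <- if (n_categories <= length(base))
      names(base)[seq_len(n_categories)]
    else c(names(base), sprintf("cat%d", seq(length(base) + 1,
                                             n_categories)))[seq_len(n_categories)]
  }
  if (any(lengths(vocab) == 0)) {
    stop("empty_vocabulary: every category needs a non-empty name vocabulary",
         call. = FALSE)
  }
  # inject shared words to create configurable ambiguity
  if (vocab_overlap > 0) {
    pool <- shared_vocab_pool()
    n_shared <- min(length(pool),
                    max(0L, round(vocab_overlap * min(lengths(vocab)))))
    if (n_shared > 0) {
      shared <- pool[seq_len(n_shared)]
      vocab <- lapply(vocab, function(v) unique(c(v, shared)))
    }
  }
  if (is.null(ingredient_pools)) {
    base <- default_ingredient_pools()
    ingredient_pools <- lapply(seq_len(n_categories), function(c) {
      if (c <= length(base)) base[[c]]
      else sprintf("ing%d%s", c, letters[1:25])
    })
  }
  if (any(lengths(ingredient_pools) == 0)) {
    stop("empty_vocabulary: every category needs a non-empty ingredient pool",
         call. = FALSE)
  }
  if (length(target_rrr_macro) != n_categories) {
    target_rrr_macro <- seq(0.3, 1.5, length.out = n_categories)
  }
  if (is.null(nutrient_means)) {
    arch <- default_category_archetypes()
    nutrient_means <- lapply(seq_len(n_categories), function(c) {
      a <- arch[[((c - 1) %% length(arch)) + 1]]
      profile_for_rrr_macro(target_rrr_macro[c], a)
    })
  }
  ok <- vapply(nutrient_means, function(p) all(unclass(p) > 0), logical(1))
  if (!all(ok)) stop("nutrient means must be strictly positive", call. = FALSE)
  if (name_length_range[1] < 1 ||
      name_length_range[2] < name_length_range[1]) {
    stop("invalid name_length_range", call. = FALSE)
  }
  structure(list(
    n_categories = as.integer(n_categories),
    items_per_category = as.integer(items_per_category),
    vocab = vocab, ingredient_pools = ingredient_pools,
    nutrient_means = nutrient_means,
    target_rrr_macro = target_rrr_macro,
    nutrient_cv = nutrient_cv, word_effect_sd = word_effect_sd,
    ingredient_align = ingredient_align,
    vocab_overlap = vocab_overlap,
    name_length_range = as.integer(name_length_range),
    ingredients_range = as.integer(ingredients_range),
    seed = as.integer(seed)
  ), class = "mint_synthetic_config")
}

#' Generate a synthetic food-item corpus
#'
#' Draws `n_categories x items_per_category` items. Names are sampled
#' without replacement from the item's category vocabulary, ingredients
#' from the category pool, and nutrient amounts log-normally around the
#' category mean (mean-preserving parameterization, so the expected
#' amount equals the category mean). Per-word healthiness effects
#' multiply protein and fiber. Identical (config, seed) gives identical
#' output.
#'
#' @param config [synthetic_config()].
#' @return object of class `mint_synthetic_corpus`: list with `items`
#'   (data.frame: item_id, name, ingredients, true_category, nutrient
#'   columns, rrr, rrr_macro) and the `config`.
#' @export
generate_food_items <- function(config) {
  stopifnot(inherits(config, "mint_synthetic_config"))
  with_seed(config$seed, {
    K <- config$n_categories
    m <- config$items_per_category
    sdlog <- sqrt(log(1 + config$nutrient_cv^2))
    keys <- names(daily_values())
    # category-specific per-word effects (log scale), centered within
    # each vocabulary so they model within-category variation without
    # shifting the planted category mean
    word_effects <- lapply(seq_len(K), function(c) {
      v <- config$vocab[[c]]
      e <- stats::rnorm(length(v), 0, config$word_effect_sd)
      stats::setNames(e - mean(e), v)
    })
    # per-ingredient healthiness coefficients (log scale, centered):
    # items with healthier names sample healthier ingredients, so the
    # name-level effects leave a learnable footprint in recipe text
    ingredient_effects <- lapply(seq_len(K), function(c) {
      p <- config$ingredient_pools[[c]]
      g <- stats::rnorm(length(p), 0, config$word_effect_sd)
      stats::setNames(g - mean(g), p)
    })
    rows <- vector("list", K * m)
    profiles <- vector("list", K * m)
    idx <- 0L
    for (c in seq_len(K)) {
      vocab <- config$vocab[[c]]
      pool <- config$ingredient_pools[[c]]
      mu <- unclass(config$nutrient_means[[c]])
      names_c <- vector("list", m)
      ings_c <- vector("list", m)
      mult <- numeric(m)
      for (i in seq_len(m)) {
        nlr <- config$name_length_range
        len <- sample(seq(nlr[1], min(nlr[2], length(vocab))), 1)
        names_c[[i]] <- sample(vocab, len)
        ir <- config$ingredients_range
        n_ing <- sample(seq(ir[1], min(ir[2], length(pool))), 1)
        e_i <- mean(word_effects[[c]][names_c[[i]]])
        w_ing <- exp(config$ingredient_align * e_i *
                       ingredient_effects[[c]])
        ings_c[[i]] <- sample(pool, n_ing, prob = w_ing)
        mult[i] <- exp(e_i)
      }
      # renormalize so the category's mean multiplier is exactly 1:
      # name-linked variation must not shift the planted category mean
      if (config$word_effect_sd > 0) mult <- mult / mean(mult)
      for (i in seq_len(m)) {
        idx <- idx + 1L
        amounts <- mu[keys]
        if (sdlog > 0) {
          noise <- exp(stats::rnorm(length(keys), -sdlog^2 / 2, sdlog))
          amounts <- amounts * noise
        }
        amounts[c("protein", "fiber")] <-
          amounts[c("protein", "fiber")] * mult[i]
        p <- nutrient_profile(as.list(amounts))
        profiles[[idx]] <- p
        rows[[idx]] <- data.frame(
          item_id = idx,
          name = paste(names_c[[i]], collapse = " "),
          ingredients = paste(ings_c[[i]], collapse = ";"),
          true_category = c,
          stringsAsFactors = FALSE
        )
      }
    }
    items <- do.call(rbind, rows)
    items <- cbind(items, profiles_to_columns(profiles))
    items$rrr <- vapply(profiles, function(p)
      as.numeric(compute_rrr(p)), numeric(1))
    items$rrr_macro <- vapply(profiles, function(p)
      as.numeric(compute_rrr_macro(p)), numeric(1))
    structure(list(items = items, config = config),
              class = "mint_synthetic_corpus")
  })
}

#' @export
print.mint_synthetic_corpus <- function(x, ...) {
  cat("Synthetic food corpus:", nrow(x$items), "items,",
      x$config$n_categories, "categories\n")
  invisible(x)
}

recipe_filler_templates <- function() {
  c("combine %s and %s in a bowl and mix well",
    "cook the %s with %s over medium heat until done",
    "layer the %s then top with %s and serve warm",
    "whisk %s into the %s and let it rest",
    "toss the %s with %s and season to taste",
    "bake with %s and %s until golden then cool")
}

#' Build the recipe-style training corpus
#'
#' One text document per item: the item name, its ingredient words, and
#' (optionally) a short templated preparation sentence, emulating the
#' name + ingredients + instructions structure of recipe datasets used
#' to train food-language embeddings. Template choice cycles
#' deterministically with item index.
#'
#' @param corpus [generate_food_items()] output.
#' @param include_filler include templated instruction text.
#' @return character vector of documents, one per item, with attribute
#'   `n_tokens` (total token count).
#' @export
generate_recipe_corpus <- function(corpus, include_filler = TRUE) {
  stopifnot(inherits(corpus, "mint_synthetic_corpus"))
  items <- corpus$items
  if (nrow(items) == 0) stop("empty corpus", call. = FALSE)
  templates <- recipe_filler_templates()
  docs <- vapply(seq_len(nrow(items)), function(i) {
    ings <- strsplit(items$ingredients[i], ";", fixed = TRUE)[[1]]
    doc <- paste(items$name[i], paste(ings, collapse = " "))
    if (include_filler && length(ings) >= 2) {
      tpl <- templates[((i - 1) %% length(templates)) + 1]
      doc <- paste(doc, sprintf(tpl, ings[1], ings[2]))
    }
    doc
  }, character(1))
  attr(docs, "n_tokens") <- sum(lengths(tokenize_text(docs)))
  docs
}

#' Generate synthetic restaurant menus
#'
#' Each restaurant has a category mix (weights over the latent
#' categories); its menu items are drawn from the corpus according to
#' that mix, so restaurants skewed toward high-RRRmacro categories have
#' higher true restaurant nutrient density.
#'
#' @param corpus [generate_food_items()] output.
#' @param n_restaurants number of restaurants.
#' @param menu_size_range integer (min, max) menu length.
#' @param category_mix `NULL` (random Dirichlet(1) mixes), a single
#'   weight vector recycled for all restaurants, or a matrix with one
#'   row per restaurant. Rows must sum to 1.
#' @param seed integer seed.
#' @return data.frame: restaurant_id, item_name, true_category,
#'   rrr_macro; the mix matrix is attached as attribute `category_mix`.
#' @export
generate_restaurants <- function(corpus, n_restaurants = 20,
                                 menu_size_range = c(10L, 30L),
                                 category_mix = NULL, seed = 1L) {
  stopifnot(inherits(corpus, "mint_synthetic_corpus"))
  if (menu_size_range[1] < 1) {
    stop("invalid_menu_size: menu_size_range min must be >= 1",
         call. = FALSE)
  }
  K <- corpus$config$n_categories
  with_seed(seed, {
    if (is.null(category_mix)) {
      g <- matrix(stats::rexp(n_restaurants * K), n_restaurants, K)
      category_mix <- g / rowSums(g)
    } else if (is.null(dim(category_mix))) {
      category_mix <- matrix(category_mix, n_restaurants, K, byrow = TRUE)
    }
    if (any(abs(rowSums(category_mix) - 1) > 1e-8)) {
      stop("invalid_weights: category mixes must sum to 1 per restaurant",
           call. = FALSE)
    }
    by_cat <- split(seq_len(nrow(corpus$items)),
                    corpus$items$true_category)
    rows <- lapply(seq_len(n_restaurants), function(r) {
      m <- if (menu_size_range[2] > menu_size_range[1]) {
        sample(seq(menu_size_range[1], menu_size_range[2]), 1)
      } else menu_size_range[1]
      cats <- sample.int(K, m, replace = TRUE, prob = category_mix[r, ])
      pick <- vapply(cats, function(c) {
        ids <- by_cat[[as.character(c)]]
        ids[sample.int(length(ids), 1)]
      }, integer(1))
      data.frame(
        restaurant_id = sprintf("R%03d", r),
        item_name = corpus$items$name[pick],
        true_category = cats,
        rrr_macro = corpus$items$rrr_macro[pick],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "category_mix") <- category_mix
    out
  })
}
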