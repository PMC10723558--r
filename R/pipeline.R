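# End-to-end pipeline glue: schema-validated config, stage sequencing,
# artifact + manifest writing. A single global seed fans out to
# stage-specific seeds (seed + stage index) so stages can be rerun in
# isolation.

pipeline_defaults <- function() {
  list(
    paths = list(items = NULL, corpus = NULL, menus = NULL,
                 regions = NULL, out = NULL),
    variant = "rrr_macro",
    missing = "error",
    seed = 1L,
    embedding = list(dim = 300, epochs = 5, window = 5, negative = 5,
                     lr = 0.05, min_count = 1),
    reducer = list(method = "umap", n_components = 2, n_neighbors = 15),
    clusterer = list(min_samples = 10, min_cluster_size = NULL,
                     cluster_selection_epsilon = 0),
    mlp = list(),
    finetune = list(min_finetune_items = 20),
    predict = list(n_mc = 100, ci_method = "percentile",
                   routing = "hard"),
    rnd = list(contamination = 0.03, filter = FALSE)
  )
}

#' Validate a pipeline configuration
#'
#' Merges a user config (list, or path to a YAML file) over the
#' defaults. Unknown keys at any level are rejected; required paths are
#' checked before any computation, naming the missing field.
#'
#' @param config list or YAML file path.
#' @return validated config list (class `mint_pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  check_keys <- function(user, ref, prefix = "") {
    unknown <- setdiff(names(user), names(ref))
    if (length(unknown)) {
      stop("config_error: unknown key(s) ",
           paste0(prefix, unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
          is.list(user[[k]])) {
        check_keys(user[[k]], ref[[k]], paste0(prefix, k, "$"))
      }
    }
  }
  # mlp keys validated against mlp_config's formals
  ref <- defaults
  ref$mlp <- formals(mlp_config)
  check_keys(config, ref)
  cfg <- utils::modifyList(defaults, config)
  for (field in c("items", "out")) {
    if (is.null(cfg$paths[[field]])) {
      stop("config_error: required field paths$", field, " is missing",
           call. = FALSE)
    }
  }
  if (!cfg$variant %in% c("rrr_macro", "rrr")) {
    stop("config_error: variant must be rrr_macro or rrr", call. = FALSE)
  }
  class(cfg) <- "mint_pipeline_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage_", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prediction pipeline
#'
#' Executes embedding training, pseudo-labeling, category-predictor and
#' regressor training, per-category fine-tuning, menu prediction and
#' restaurant aggregation, writing versioned artifacts and a run
#' manifest (resolved config, stage seeds, input checksums, timings) to
#' the output directory. Reruns with an identical config produce
#' byte-identical prediction files.
#'
#' @param config list or YAML path, see [pipeline_config()].
#' @return invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(if (inherits(config, "mint_pipeline_config"))
    unclass(config) else config)
  out_dir <- cfg$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    t <- system.time(res <- pipeline_stage(name, expr))
    timings[[name]] <<- unname(t["elapsed"])
    message(sprintf("[mintr] stage %-18s %6.1fs", name, t["elapsed"]))
    res
  }
  artifacts <- list()

  items <- tick("read_items", {
    it <- read_items(cfg$paths$items)
    score_items(it, variant = cfg$variant, missing = cfg$missing)
  })

  docs <- tick("corpus", {
    if (!is.null(cfg$paths$corpus)) {
      readLines(cfg$paths$corpus, encoding = "UTF-8", warn = FALSE)
    } else {
      # fall back to context sentences built from the item table
      vapply(seq_len(nrow(items)), function(i) {
        ings <- if ("ingredients" %in% names(items)) {
          strsplit(items$ingredients[i], ";", fixed = TRUE)[[1]]
        } else character(0)
        build_context_sentence(items$name[i], ings)
      }, character(1))
    }
  })

  emb <- tick("embeddings", do.call(train_embedding_model, c(
    list(corpus = docs, seed = stage_seed(cfg$seed, 1)), cfg$embedding)))
  artifacts$embedding <- file.path(out_dir, "embedding_model.rds")
  save_embedding_model(emb, artifacts$embedding)
  artifacts$word_vectors <- file.path(out_dir, "word_vectors.txt")
  write_word_vectors(emb, artifacts$word_vectors)

  pl <- tick("pseudo_labels", {
    sentences <- vapply(seq_len(nrow(items)), function(i) {
      ings <- if ("ingredients" %in% names(items)) {
        strsplit(items$ingredients[i], ";", fixed = TRUE)[[1]]
      } else character(0)
      build_context_sentence(items$name[i], ings)
    }, character(1))
    ctx <- embed_context(context_encoder(emb), sentences)
    fit_pseudo_labels(ctx, cfg$reducer, cfg$clusterer,
                      seed = stage_seed(cfg$seed, 2))
  })
  artifacts$pseudo_labels <- file.path(out_dir, "pseudo_labels.csv")
  pl_df <- data.frame(item_id = seq_along(pl$hard_label),
                      hard_label = pl$hard_label,
                      is_noise = pl$is_noise)
  pmat <- as.data.frame(pl$membership)
  names(pmat) <- sprintf("p_%d", seq_len(ncol(pmat)) - 1L)
  utils::write.csv(cbind(pl_df, round(pmat, 6)),
                   artifacts$pseudo_labels, row.names = FALSE)

  name_vecs <- embed_name(emb, items$name)
  mlp_cfg <- do.call(mlp_config, cfg$mlp)

  predictor <- tick("category_predictor",
                    train_category_predictor(name_vecs, pl, config = mlp_cfg,
                                             seed = stage_seed(cfg$seed, 3)))
  regressor <- tick("global_regressor",
                    train_global_regressor(name_vecs, items$score,
                                           config = mlp_cfg,
                                           variant = cfg$variant,
                                           seed = stage_seed(cfg$seed, 4)))
  ensemble <- tick("finetune", {
    labs <- pl$hard_label * (!pl$is_noise)
    finetune_per_category(regressor, name_vecs, items$score, labs,
                          min_finetune_items = cfg$finetune$min_finetune_items,
                          seed = stage_seed(cfg$seed, 5))
  })
  artifacts$checkpoint <- file.path(out_dir, "checkpoint.rds")
  saveRDS(list(predictor = predictor, regressor = regressor,
               ensemble = ensemble, variant = cfg$variant),
          artifacts$checkpoint)

  target_names <- if (!is.null(cfg$paths$menus)) {
    read_menus(cfg$paths$menus)
  } else {
    data.frame(restaurant_id = NA_character_, item_name = items$name,
               stringsAsFactors = FALSE)
  }
  preds <- tick("predict", predict_with_uncertainty(
    ensemble, predictor, emb, target_names$item_name,
    n_mc = cfg$predict$n_mc, ci_method = cfg$predict$ci_method,
    routing = cfg$predict$routing, seed = stage_seed(cfg$seed, 6)))
  preds_out <- cbind(restaurant_id = target_names$restaurant_id,
                     as.data.frame(preds))
  artifacts$predictions <- file.path(out_dir, "predictions.csv")
  write_predictions(preds_out, artifacts$predictions)

  if (!is.null(cfg$paths$menus)) {
    rnd <- tick("rnd", {
      menu_scores <- data.frame(restaurant_id = preds_out$restaurant_id,
                                rrr_macro = preds_out$score)
      restaurant_rnd(menu_scores, filter = cfg$rnd$filter,
                     contamination = cfg$rnd$contamination)
    })
    artifacts$rnd <- file.path(out_dir, "rnd.csv")
    utils::write.csv(rnd, artifacts$rnd, row.names = FALSE)
    if (!is.null(cfg$paths$regions)) {
      regions <- aggregate_by_region(rnd, read_region_map(cfg$paths$regions))
      artifacts$regions <- file.path(out_dir, "regions.csv")
      utils::write.csv(regions, artifacts$regions, row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mintr")),
    config = unclass(cfg),
    stage_seeds = stats::setNames(
      lapply(1:6, function(k) stage_seed(cfg$seed, k)),
      c("embeddings", "pseudo_labels", "category_predictor",
        "global_regressor", "finetune", "predict")),
    input_checksums = as.list(tools::md5sum(stats::na.omit(unlist(
      cfg$paths[c("items", "corpus", "menus", "regions")])))),
    timings = timings,
    total_elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  artifacts$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(artifacts)
}
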