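# Restaurant-level aggregation: histogram-based outlier filtering of
# item scores, Restaurant Nutrient Density (median menu RRRmacro), and
# region summaries.

#' Histogram-based outlier filtering
#'
#' Computes a histogram-based outlier score per point — the negative
#' log density of its equal-width histogram bin (bin count =
#' `round(sqrt(n))` by default) — and removes the top `contamination`
#' fraction by score. Matches the roughly 3% of extreme menu-item
#' scores removed from real ground-truth pools. Deterministic: ties are
#' broken by input position.
#'
#' @param scores numeric vector.
#' @param contamination fraction removed, in `[0, 0.5)`.
#' @param n_bins histogram bin count (default `round(sqrt(n))`).
#' @return list with `kept` (surviving scores), `removed` (indices into
#'   the input) and `outlier_score` per input point.
#' @export
filter_outliers <- function(scores, contamination = 0.03, n_bins = NULL) {
  if (length(scores) == 0) stop("empty_input", call. = FALSE)
  if (contamination < 0 || contamination >= 0.5) {
    stop("contamination must be in [0, 0.5)", call. = FALSE)
  }
  n <- length(scores)
  if (is.null(n_bins)) n_bins <- max(1L, as.integer(round(sqrt(n))))
  rng <- range(scores)
  if (rng[2] == rng[1]) {
    os <- rep(0, n)
  } else {
    width <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((scores - rng[1]) / width) + 1L, n_bins)
    dens <- tabulate(bin, nbins = n_bins) / (n * width)
    os <- -log(dens[bin])
  }
  k <- floor(contamination * n)
  removed <- if (k > 0) order(-os, seq_len(n))[seq_len(k)] else integer(0)
  kept <- if (k > 0) scores[-removed] else scores
  list(kept = kept, removed = sort(removed), outlier_score = os)
}

#' Restaurant Nutrient Density (RND)
#'
#' The median of a restaurant menu's per-item RRRmacro scores
#' (even-length medians are the midpoint of the two middle order
#' statistics). Outlier filtering is optional and off by default: it is
#' intended for ground-truth score pools, not predictions.
#'
#' @param scores numeric item scores for one menu.
#' @param restaurant_id optional identifier carried into the result.
#' @param filter apply [filter_outliers()] first.
#' @param contamination passed to [filter_outliers()].
#' @return list of class `mint_rnd`: `restaurant_id`, `value`,
#'   `n_items`, `n_removed`.
#' @export
compute_rnd <- function(scores, restaurant_id = NA_character_,
                        filter = FALSE, contamination = 0.03) {
  if (length(scores) == 0) stop("empty_input: menu has no items",
                                call. = FALSE)
  removed <- 0L
  if (filter) {
    f <- filter_outliers(scores, contamination)
    removed <- length(f$removed)
    scores <- f$kept
  }
  if (length(scores) == 0) {
    stop("all_items_removed: no surviving menu items", call. = FALSE)
  }
  structure(list(restaurant_id = restaurant_id,
                 value = stats::median(scores),
                 n_items = length(scores), n_removed = removed),
            class = "mint_rnd")
}

#' RND for every restaurant in a menu table
#'
#' @param menus data.frame with `restaurant_id` and a score column.
#' @param score_col score column name (default `"rrr_macro"`).
#' @param filter,contamination see [compute_rnd()].
#' @return data.frame: `restaurant_id, rnd, n_items, n_removed`.
#' @export
restaurant_rnd <- function(menus, score_col = "rrr_macro",
                           filter = FALSE, contamination = 0.03) {
  stopifnot(score_col %in% names(menus))
  ids <- unique(menus$restaurant_id)
  rows <- lapply(ids, function(id) {
    r <- compute_rnd(menus[[score_col]][menus$restaurant_id == id],
                     restaurant_id = id, filter = filter,
                     contamination = contamination)
    data.frame(restaurant_id = id, rnd = r$value, n_items = r$n_items,
               n_removed = r$n_removed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate RND over regions
#'
#' Arithmetic mean of restaurant RND per region; restaurants missing
#' from the region map are reported under region `NA`.
#'
#' @param rnd_scores data.frame from [restaurant_rnd()] (columns
#'   `restaurant_id`, `rnd`).
#' @param region_map data.frame with `restaurant_id, region`.
#' @return data.frame: `region, mean_rnd, n_restaurants`, sorted by
#'   region with the unmapped row (if any) last.
#' @export
aggregate_by_region <- function(rnd_scores, region_map) {
  region <- region_map$region[match(rnd_scores$restaurant_id,
                                    region_map$restaurant_id)]
  key <- ifelse(is.na(region), "\001unmapped", region)
  agg <- stats::aggregate(rnd_scores$rnd, by = list(key = key),
                          FUN = mean)
  cnt <- as.data.frame(table(key), stringsAsFactors = FALSE)
  out <- data.frame(
    region = ifelse(agg$key == "\001unmapped", NA_character_, agg$key),
    mean_rnd = agg$x,
    n_restaurants = cnt$Freq[match(agg$key, cnt$key)],
    stringsAsFactors = FALSE
  )
  out <- out[order(is.na(out$region), out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
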