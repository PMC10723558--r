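# Tabular IO: food item tables, predictions, menus, region maps.
# All files are UTF-8 CSV with standard quoting so names containing
# commas or unicode survive round-trips.

# canonical column <-> nutrient key map for item tables
nutrient_columns <- function() {
  c(protein = "protein_g", fiber = "fiber_g", vitamin_a = "vitamin_a_ug",
    vitamin_c = "vitamin_c_mg", calcium = "calcium_mg", iron = "iron_mg",
    calories = "calories_kcal", total_sugar = "sugar_g",
    cholesterol = "cholesterol_mg", saturated_fat = "satfat_g",
    sodium = "sodium_mg")
}

#' Read a food-item table
#'
#' Reads a CSV (or JSON array of records) with a `name` column and
#' optional nutrient columns `protein_g, fiber_g, vitamin_a_ug,
#' vitamin_c_mg, calcium_mg, iron_mg, calories_kcal, sugar_g,
#' cholesterol_mg, satfat_g, sodium_mg`. Malformed rows (missing name,
#' negative or non-numeric nutrient amounts) are collected and reported
#' with their line numbers rather than silently dropped.
#'
#' @param path file path (`.csv` or `.json`).
#' @param on_error `"stop"` (default) raises with the full error list;
#'   `"report"` returns valid rows and attaches the error report as
#'   attribute `row_errors`.
#' @return data.frame of items.
#' @export
read_items <- function(path, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = TRUE)
  }
  if (!"name" %in% names(df)) {
    stop("items table must have a 'name' column", call. = FALSE)
  }
  errors <- character(0)
  bad <- rep(FALSE, nrow(df))
  # line number in file = data row index + 1 (header)
  miss_name <- is.na(df$name) | trimws(df$name) == ""
  if (any(miss_name)) {
    errors <- c(errors, sprintf("line %d: empty item name",
                                which(miss_name) + 1L))
    bad <- bad | miss_name
  }
  for (col in intersect(nutrient_columns(), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    neg <- !is.na(v) & v < 0
    nonnum <- is.na(v) & !is.na(df[[col]]) & trimws(df[[col]]) != ""
    if (any(neg)) {
      errors <- c(errors, sprintf("line %d: negative %s (%s)",
                                  which(neg) + 1L, col, df[[col]][neg]))
      bad <- bad | neg
    }
    if (any(nonnum)) {
      errors <- c(errors, sprintf("line %d: non-numeric %s ('%s')",
                                  which(nonnum) + 1L, col, df[[col]][nonnum]))
      bad <- bad | nonnum
    }
    df[[col]] <- v
  }
  if (length(errors) && on_error == "stop") {
    stop("malformed rows in ", path, ":\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (length(errors)) attr(out, "row_errors") <- errors
  out
}

#' @rdname read_items
#' @param items data.frame with a `name` column.
#' @export
write_items <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# item table rows -> list of nutrient_profile
items_to_profiles <- function(items) {
  cols <- nutrient_columns()
  lapply(seq_len(nrow(items)), function(i) {
    amounts <- list()
    for (k in names(cols)) {
      col <- cols[[k]]
      if (col %in% names(items) && !is.na(items[[col]][i])) {
        amounts[[k]] <- items[[col]][i]
      }
    }
    nutrient_profile(amounts)
  })
}

# named profile list -> item table columns
profiles_to_columns <- function(profiles) {
  cols <- nutrient_columns()
  mat <- do.call(rbind, lapply(profiles, function(p) unclass(p)[names(cols)]))
  colnames(mat) <- unname(cols)
  as.data.frame(mat)
}

#' Write model predictions
#'
#' Writes the `name, predicted_category, score, ci_low, ci_high`
#' prediction table produced by [predict_with_uncertainty()]. Numeric
#' columns are formatted with full precision so reruns under the same
#' seed are byte-identical.
#'
#' @param results prediction data.frame.
#' @param path output CSV path.
#' @export
write_predictions <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Read a restaurant menu table
#'
#' CSV with columns `restaurant_id, item_name[, rrr_macro]`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_menus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("restaurant_id", "item_name")
  if (!all(need %in% names(df))) {
    stop("menu table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a restaurant-to-region map
#'
#' CSV with columns `restaurant_id, region`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("restaurant_id", "region")
  if (!all(need %in% names(df))) {
    stop("region map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
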