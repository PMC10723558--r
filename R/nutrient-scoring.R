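#' FDA daily values for the eleven RRR nutrients
#'
#' Returns the daily-value (DV) intake table used to express nutrient
#' amounts as percentages of the FDA recommended daily value. Six
#' nutrients are *recommended* (protein, fiber, vitamin A, vitamin C,
#' calcium, iron) and five are *restricted* (calories, total sugar,
#' cholesterol, saturated fat, sodium).
#'
#' Units are fixed: grams for protein, fiber, total sugar and saturated
#' fat; milligrams for vitamin C, calcium, iron, cholesterol and sodium;
#' micrograms for vitamin A; kcal for calories. No unit conversion is
#' performed anywhere in the package.
#'
#' @return named numeric vector of length 11 with attributes
#'   `recommended` and `restricted` listing the two nutrient sets.
#' @export
#' @examples
#' daily_values()[["protein"]]  # 50 g
daily_values <- function() {
  dv <- c(
    protein = 50, fiber = 28, vitamin_a = 900, vitamin_c = 90,
    calcium = 1300, iron = 18,
    calories = 2000, total_sugar = 50, cholesterol = 300,
    saturated_fat = 20, sodium = 2300
  )
  attr(dv, "recommended") <- c("protein", "fiber", "vitamin_a", "vitamin_c",
                               "calcium", "iron")
  attr(dv, "restricted") <- c("calories", "total_sugar", "cholesterol",
                              "saturated_fat", "sodium")
  dv
}

#' Recommended / restricted nutrient keys
#' @rdname daily_values
#' @export
recommended_nutrients <- function() attr(daily_values(), "recommended")

#' @rdname daily_values
#' @export
restricted_nutrients <- function() attr(daily_values(), "restricted")

#' Percent of daily value
#'
#' `100 * amount / DV(nutrient)`, the scale on which both nutrient
#' density indices are defined (100 = exactly the daily value).
#'
#' @param amount numeric amount(s) in Table-standard units (see
#'   [daily_values()]).
#' @param nutrient nutrient key, one of the eleven DV nutrients.
#' @param dv daily-value table, defaults to [daily_values()].
#' @return numeric percentage(s).
#' @export
#' @examples
#' percent_dv(50, "protein")  # 100
#' percent_dv(14, "fiber")    # 50
percent_dv <- function(amount, nutrient, dv = daily_values()) {
  if (length(nutrient) != 1 || !nutrient %in% names(dv)) {
    stop("unknown_nutrient: '", paste(nutrient, collapse = ","),
         "' is not one of the 11 daily-value nutrients", call. = FALSE)
  }
  amount <- as.numeric(amount)
  if (any(!is.finite(amount)) || any(amount < 0)) {
    stop("negative_amount: nutrient amounts must be finite and >= 0",
         call. = FALSE)
  }
  100 * amount / dv[[nutrient]]
}

#' Construct a nutrient profile
#'
#' A nutrient profile is a named numeric vector over the eleven DV
#' nutrient keys; `NA` marks a missing measurement.
#'
#' @param ... named nutrient amounts, or a single named vector/list.
#' @return named numeric vector of length 11 (class `nutrient_profile`).
#' @export
#' @examples
#' nutrient_profile(protein = 50, fiber = 28, calories = 2000,
#'                  total_sugar = 50, cholesterol = 300,
#'                  saturated_fat = 20, sodium = 2300)
nutrient_profile <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) &&
      (is.list(args[[1]]) || !is.null(names(args[[1]])))) {
    args <- as.list(args[[1]])
  }
  keys <- names(daily_values())
  unknown <- setdiff(names(args), keys)
  if (length(unknown)) {
    stop("unknown_nutrient: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (k in names(args)) p[[k]] <- as.numeric(args[[k]])
  present <- !is.na(p)
  if (any(!is.finite(p[present])) || any(p[present] < 0)) {
    stop("negative_amount: present amounts must be finite and >= 0",
         call. = FALSE)
  }
  class(p) <- c("nutrient_profile", "numeric")
  p
}

# resolve missing values per policy; returns plain named numeric
resolve_missing <- function(profile, needed, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  p <- unclass(profile)[needed]
  if (anyNA(p)) {
    if (missing == "error") {
      stop("missing_nutrient: ", paste(needed[is.na(p)], collapse = ", "),
           " absent and missing policy is 'error'", call. = FALSE)
    }
    p[is.na(p)] <- 0
  }
  p
}

rrr_core <- function(profile, numerator_keys, dv, missing, max_score, variant) {
  restricted <- restricted_nutrients()
  amounts <- resolve_missing(profile, c(numerator_keys, restricted), missing)
  pdv <- 100 * amounts / dv[names(amounts)]
  num <- mean(pdv[numerator_keys])
  den <- mean(pdv[restricted])
  if (den == 0) {
    stop("undefined_denominator: mean restricted %DV is zero", call. = FALSE)
  }
  value <- num / den
  if (!is.null(max_score)) value <- min(value, max_score)
  structure(value, variant = variant)
}

#' RRR nutrient density score
#'
#' Ratio of recommended to restricted nutrients: the mean %DV of the six
#' recommended nutrients divided by the mean %DV of the five restricted
#' nutrients. The score is portion-size invariant (scaling every amount
#' by the same constant leaves it unchanged) and equals 1 for a food at
#' exactly the daily value for every nutrient.
#'
#' @param profile [nutrient_profile()] (or named numeric vector).
#' @param dv daily-value table.
#' @param missing `"error"` (default) stops on a missing required
#'   nutrient; `"zero"` treats missing as amount 0 (useful for sparse
#'   menu data).
#' @param max_score optional cap on the returned value (default none).
#' @return numeric score with attribute `variant`.
#' @seealso [compute_rrr_macro()] for the macronutrient-only variant.
#' @export
compute_rrr <- function(profile, dv = daily_values(),
                        missing = c("error", "zero"), max_score = NULL) {
  rrr_core(profile, recommended_nutrients(), dv, match.arg(missing),
           max_score, "RRR")
}

#' RRRmacro nutrient density score
#'
#' RRR with the micronutrients dropped from the numerator: mean %DV of
#' protein and fiber over mean %DV of the five restricted nutrients.
#' Intended for datasets whose micronutrient values are sparse or
#' unreliable.
#'
#' @inheritParams compute_rrr
#' @return numeric score with attribute `variant`.
#' @export
compute_rrr_macro <- function(profile, dv = daily_values(),
                              missing = c("error", "zero"),
                              max_score = NULL) {
  rrr_core(profile, c("protein", "fiber"), dv, match.arg(missing),
           max_score, "RRRmacro")
}

#' Score a table of food items
#'
#' Applies [compute_rrr()] or [compute_rrr_macro()] row-wise to an item
#' table as read by [read_items()].
#'
#' @param items data.frame with nutrient columns (`protein_g`, ...,
#'   `sodium_mg`; see [read_items()]).
#' @param variant `"rrr"` or `"rrr_macro"`.
#' @param missing missing-nutrient policy, see [compute_rrr()].
#' @return `items` with a `score` column appended.
#' @export
score_items <- function(items, variant = c("rrr_macro", "rrr"),
                        missing = c("error", "zero")) {
  variant <- match.arg(variant)
  missing <- match.arg(missing)
  profiles <- items_to_profiles(items)
  fun <- if (variant == "rrr") compute_rrr else compute_rrr_macro
  items$score <- vapply(profiles, function(p)
    as.numeric(fun(p, missing = missing)), numeric(1))
  items
}
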