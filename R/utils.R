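#' @useDynLib mintr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Single global seed fans out to stage-specific seeds (seed + stage index),
# kept inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage) %% 2147483647)
}

#' Normalize and tokenize food text
#'
#' Lowercases, strips punctuation, collapses whitespace and splits on
#' spaces. This is the single tokenization used throughout the package
#' (name averaging, corpus training, context sentences).
#'
#' @param x character vector.
#' @return list of character vectors (tokens per element).
#' @export
tokenize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^[:alnum:]]+", " ", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  strsplit(x, " ", fixed = TRUE)
}

# argmax with ties broken by lowest index
arg_max <- function(x) which.max(x)

#' Adjusted Rand index between two labelings
#'
#' Standard pair-counting ARI; used to compare cluster assignments with
#' planted category truth.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# weighted quantile helpers are not needed; stats::quantile type 7 is used
# everywhere an interval percentile is taken.
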