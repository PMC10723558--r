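# Food-category pseudo-labels: reduce ingredient-contextualized
# embeddings to 2-D, soft-cluster them, then train a name-only network
# that predicts the category distribution for unseen items.

#' Fit food-category pseudo-labels
#'
#' Reduces context embeddings (typically from [embed_context()] over
#' [build_context_sentence()] output) to a low-dimensional space and
#' soft-clusters them. Every point receives a membership vector over
#' the discovered clusters; points belonging to no cluster are flagged
#' noise. Deterministic under `seed`.
#'
#' @param context_vectors embedding matrix, one row per item.
#' @param reducer_params list: `method` ("umap"/"pca"), `n_components`
#'   (default 2), `n_neighbors` (default 15).
#' @param clusterer_params list: `min_samples` (default 10),
#'   `min_cluster_size` (default [default_min_cluster_size()]),
#'   `cluster_selection_epsilon` (default 0), `label_weight`.
#' @param seed integer seed.
#' @return list of class `mint_pseudo_labels`: `membership` (n x k),
#'   `hard_label` (argmax, ties to the lowest cluster index),
#'   `is_noise`, `n_clusters`, `reduced` coordinates, and the fitted
#'   `cluster_model`.
#' @export
fit_pseudo_labels <- function(context_vectors, reducer_params = list(),
                              clusterer_params = list(), seed = 1L) {
  X <- as.matrix(context_vectors)
  rp <- utils::modifyList(
    list(method = "umap", n_components = 2, n_neighbors = 15), reducer_params)
  cp <- utils::modifyList(
    list(min_samples = 10, min_cluster_size = NULL,
         cluster_selection_epsilon = 0, allow_single_cluster = FALSE,
         label_weight = 0.6), clusterer_params)
  mcs <- if (is.null(cp$min_cluster_size)) default_min_cluster_size(nrow(X))
         else cp$min_cluster_size
  if (nrow(X) < 2 * mcs) {
    stop("too_few_points: need >= 2 * min_cluster_size points",
         call. = FALSE)
  }
  red <- reduce_embeddings(X, method = rp$method,
                           n_components = rp$n_components,
                           n_neighbors = rp$n_neighbors, seed = seed)
  cl <- mint_hdbscan(red, min_samples = cp$min_samples,
                     min_cluster_size = mcs,
                     cluster_selection_epsilon = cp$cluster_selection_epsilon,
                     allow_single_cluster = cp$allow_single_cluster,
                     label_weight = cp$label_weight)
  hard <- apply(cl$membership, 1, arg_max)
  hard[!cl$is_noise] <- cl$labels[!cl$is_noise]
  structure(list(
    membership = cl$membership, hard_label = as.integer(hard),
    is_noise = cl$is_noise, n_clusters = cl$n_clusters, reduced = red,
    cluster_model = cl,
    reducer_params = rp, clusterer_params = cp, seed = seed
  ), class = "mint_pseudo_labels")
}

#' @export
print.mint_pseudo_labels <- function(x, ...) {
  cat("Pseudo-labels:", x$n_clusters, "clusters over",
      length(x$hard_label), "items;", sum(x$is_noise), "noise\n")
  invisible(x)
}

#' Train the name-only category predictor
#'
#' Five-layer network mapping name embeddings to the pseudo-label
#' category distribution, trained with softmax + cross-entropy against
#' the soft membership targets (default) or per-class sigmoid BCE
#' (`loss = "bce"`), with early stopping on a 20% validation split.
#' Noise-flagged items are excluded from training.
#'
#' @param name_vectors embedding matrix of item names.
#' @param pseudo_labels [fit_pseudo_labels()] output (or a list with
#'   `membership` and `is_noise`).
#' @param config [mlp_config()].
#' @param loss `"softmax"` (cross-entropy on soft targets) or `"bce"`.
#' @param seed integer seed.
#' @return object of class `mint_category_predictor`.
#' @export
train_category_predictor <- function(name_vectors, pseudo_labels,
                                     config = mlp_config(),
                                     loss = c("softmax", "bce"),
                                     seed = 1L) {
  loss <- match.arg(loss)
  X <- as.matrix(name_vectors)
  M <- pseudo_labels$membership
  keep <- !pseudo_labels$is_noise
  if (sum(keep) < 2) stop("too_few_points", call. = FALSE)
  X <- X[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  if (ncol(M) < 2) {
    stop("single_category: need >= 2 categories to train a predictor",
         call. = FALSE)
  }
  Y <- M / rowSums(M)
  net <- mlp_train(X, Y, config = config,
                   loss = if (loss == "softmax") "softmax_ce" else "bce",
                   seed = seed)
  structure(list(net = net, n_categories = ncol(M),
                 input_dim = ncol(X), loss = loss),
            class = "mint_category_predictor")
}

#' Predict category probabilities for name embeddings
#'
#' @param predictor [train_category_predictor()] output.
#' @param name_vectors embedding matrix (dimension must match the
#'   training embeddings).
#' @return probability matrix, one row per item (rows sum to 1; the
#'   BCE-mode sigmoid outputs are normalized to a distribution).
#' @export
predict_category <- function(predictor, name_vectors) {
  X <- as.matrix(name_vectors)
  if (ncol(X) != predictor$input_dim) {
    stop("dimension_mismatch: expected ", predictor$input_dim,
         " columns, got ", ncol(X), call. = FALSE)
  }
  P <- mlp_predict(predictor$net, X)
  P / rowSums(P)
}
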