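# Dimensionality reduction of context embeddings before clustering.
# UMAP (via uwot, single-threaded so results are reproducible under the
# R RNG) is the default; PCA is offered as a fast linear alternative.

#' Reduce embeddings to a low-dimensional space
#'
#' @param X embedding matrix (rows = items).
#' @param method `"umap"` (default) or `"pca"`.
#' @param n_components target dimension (default 2).
#' @param n_neighbors UMAP neighborhood size.
#' @param seed integer seed (UMAP layout is stochastic).
#' @return matrix (nrow(X) x n_components) with attribute `method`.
#' @export
reduce_embeddings <- function(X, method = c("umap", "pca"),
                              n_components = 2, n_neighbors = 15,
                              seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n_components >= 2)
  # degenerate input: no variance at all
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-12)) {
    out <- matrix(0, n, n_components)
    attr(out, "method") <- "degenerate"
    return(out)
  }
  if (method == "pca") {
    p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(p$x))
    out <- p$x[, seq_len(k), drop = FALSE]
    if (k < n_components) {
      out <- cbind(out, matrix(0, n, n_components - k))
    }
    # deterministic sign convention
    for (j in seq_len(ncol(out))) {
      i <- which.max(abs(out[, j]))
      if (out[i, j] < 0) out[, j] <- -out[, j]
    }
  } else {
    nn <- max(2L, min(as.integer(n_neighbors), n - 1L))
    out <- with_seed(seed, uwot::umap(
      X, n_neighbors = nn, n_components = n_components,
      n_threads = 1, n_sgd_threads = 0, verbose = FALSE
    ))
  }
  dimnames(out) <- NULL
  attr(out, "method") <- method
  out
}
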