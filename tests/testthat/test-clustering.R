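make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(stats::rnorm(n_per, centers[k, 1], sd),
          stats::rnorm(n_per, centers[k, 2], sd))
  }))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("two far-separated blobs give exactly two clusters with ARI 1", {
  b <- make_blobs(60, rbind(c(0, 0), c(10, 10)), seed = 4)
  cl <- mint_hdbscan(b$X, min_samples = 5, min_cluster_size = 15)
  expect_identical(cl$n_clusters, 2L)
  expect_equal(adjusted_rand_index(cl$labels, b$truth), 1)
})

test_that("degenerate identical points fall back to a single cluster", {
  X <- matrix(1, 60, 2)
  cl <- mint_hdbscan(X, min_samples = 5, min_cluster_size = 10)
  expect_identical(cl$n_clusters, 1L)
  expect_true(all(cl$labels == 1L))
})

test_that("membership vectors are proper and consistent with hard labels", {
  b <- make_blobs(50, rbind(c(0, 0), c(6, 0), c(0, 6)), seed = 8)
  cl <- mint_hdbscan(b$X, min_samples = 5, min_cluster_size = 12)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  expect_equal(rowSums(cl$membership), rep(1, nrow(b$X)), tolerance = 1e-9)
  assigned <- which(!cl$is_noise)
  expect_identical(apply(cl$membership[assigned, , drop = FALSE], 1,
                         which.max),
                   cl$labels[assigned])
})

test_that("too few points raise a named error", {
  expect_error(mint_hdbscan(matrix(stats::rnorm(10), 5, 2),
                            min_cluster_size = 10), "too_few_points")
  expect_error(fit_pseudo_labels(matrix(stats::rnorm(20), 10, 2),
                                 clusterer_params =
                                   list(min_cluster_size = 10)),
               "too_few_points")
})

test_that("fit_pseudo_labels is deterministic and exposes cluster structure", {
  ctx <- small_context()
  a <- fit_pseudo_labels(ctx, reducer_params = list(method = "pca"),
                         seed = 3)
  b <- fit_pseudo_labels(ctx, reducer_params = list(method = "pca"),
                         seed = 3)
  expect_identical(a$membership, b$membership)
  expect_identical(a$hard_label, b$hard_label)
  expect_gte(a$n_clusters, 2L)
  expect_identical(apply(a$membership[!a$is_noise, , drop = FALSE], 1,
                         which.max),
                   a$hard_label[!a$is_noise])
})

test_that("pseudo-labeling recovers the planted categories on the benchmark", {
  fit <- bench_fit()
  pl <- fit$pseudo_labels
  truth <- bench_corpus()$items$true_category
  ari <- adjusted_rand_index(pl$hard_label * (!pl$is_noise), truth)
  expect_gte(ari, 0.8)
})

test_that("reducer/clusterer hyperparameters do not materially move ARI", {
  # one-at-a-time sweep over the stated grid values around the default
  # configuration, at benchmark scale
  fit <- bench_fit()
  ctx <- cache_get("bench_context", {
    corpus <- bench_corpus()
    sent <- mapply(function(n, i) {
      build_context_sentence(n, strsplit(i, ";", fixed = TRUE)[[1]])
    }, corpus$items$name, corpus$items$ingredients, USE.NAMES = FALSE)
    embed_context(context_encoder(fit$embedding), sent)
  })
  truth <- bench_corpus()$items$true_category
  ari_for <- function(rp = list(), cp = list()) {
    pl <- fit_pseudo_labels(ctx, rp, cp, seed = 2)
    adjusted_rand_index(pl$hard_label * (!pl$is_noise), truth)
  }
  aris <- c(
    dim2  = ari_for(list(n_components = 2)),
    dim10 = ari_for(list(n_components = 10)),
    dim50 = ari_for(list(n_components = 50)),
    nn10  = ari_for(list(n_neighbors = 10)),
    nn20  = ari_for(list(n_neighbors = 20)),
    nn50  = ari_for(list(n_neighbors = 50)),
    ms10  = ari_for(cp = list(min_samples = 10)),
    ms20  = ari_for(cp = list(min_samples = 20)),
    ms50  = ari_for(cp = list(min_samples = 50)),
    eps0  = ari_for(cp = list(cluster_selection_epsilon = 0)),
    eps05 = ari_for(cp = list(cluster_selection_epsilon = 0.05)),
    eps10 = ari_for(cp = list(cluster_selection_epsilon = 0.10))
  )
  expect_lt(max(aris) - min(aris), 0.1)
  expect_gte(min(aris), 0.8)
})
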