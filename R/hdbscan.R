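# Hierarchical density-based soft clustering in the reduced embedding
# space. This is a condensed-tree implementation of the HDBSCAN*
# algorithm: mutual-reachability distances with a min_samples core
# distance, single-linkage tree over the mutual-reachability MST,
# condensation by min_cluster_size, excess-of-mass cluster selection,
# and an optional cluster-selection epsilon that merges clusters born
# below a distance threshold. Soft memberships come from distances to
# per-cluster exemplars (highest-density points).

#' Default minimum cluster size
#'
#' The reference analysis used a minimum cluster size of 1000 on a
#' corpus of roughly 81k items (about 1.25%); this scales that fraction
#' down with a floor of 10 so desk-scale datasets cluster sensibly.
#'
#' @param n number of points.
#' @return integer.
#' @export
default_min_cluster_size <- function(n) max(10L, as.integer(round(0.0125 * n)))

mst_prim <- function(mr) {
  n <- nrow(mr)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_d <- mr[1, ]
  best_from <- rep(1L, n)
  best_d[1] <- Inf
  edges <- matrix(0, n - 1, 3)
  for (i in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[i, ] <- c(best_from[j], j, best_d[j])
    in_tree[j] <- TRUE
    upd <- which(!in_tree & mr[j, ] < best_d)
    best_d[upd] <- mr[j, upd]
    best_from[upd] <- j
  }
  edges
}

# single-linkage merge tree from MST edges (ascending); returns left /
# right / height arrays for merge nodes n+1 .. 2n-1 and subtree sizes
single_linkage_tree <- function(edges, n) {
  o <- order(edges[, 3], edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  comp_node <- seq_len(n)   # union-find root -> tree node id
  n_merge <- n - 1
  left <- integer(n_merge); right <- integer(n_merge)
  height <- numeric(n_merge)
  size <- c(rep(1L, n), integer(n_merge))
  for (e in seq_len(n_merge)) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    na <- comp_node[a]; nb <- comp_node[b]
    left[e] <- na; right[e] <- nb; height[e] <- edges[e, 3]
    parent[a] <- b
    comp_node[b] <- n + e
    size[n + e] <- size[na] + size[nb]
  }
  # leaf sets per node, built bottom-up (merge order is bottom-up)
  leaves <- vector("list", n + n_merge)
  for (i in seq_len(n)) leaves[[i]] <- i
  for (e in seq_len(n_merge)) {
    leaves[[n + e]] <- c(leaves[[left[e]]], leaves[[right[e]]])
  }
  list(left = left, right = right, height = height, size = size,
       leaves = leaves, n = n)
}

inv_lambda <- function(w) 1 / pmax(w, 1e-10)

#' Hierarchical density-based soft clustering
#'
#' @param X matrix of (reduced) coordinates, one row per point.
#' @param min_samples core-distance neighbor count (density smoothing).
#' @param min_cluster_size smallest allowed cluster;
#'   default [default_min_cluster_size()].
#' @param cluster_selection_epsilon distance threshold below which
#'   cluster splits are undone (0 disables).
#' @param allow_single_cluster permit selecting the root cluster.
#' @param label_weight weight of the hard assignment in the soft
#'   membership mixture (guarantees `argmax(membership) == hard label`
#'   for assigned points).
#' @return object of class `mint_hdbscan`: `labels` (0 = noise),
#'   `membership` (n x k), `is_noise`, `n_clusters`, `exemplars`,
#'   `probabilities` and the parameters used.
#' @export
mint_hdbscan <- function(X, min_samples = 10,
                         min_cluster_size = NULL,
                         cluster_selection_epsilon = 0,
                         allow_single_cluster = FALSE,
                         label_weight = 0.6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(min_cluster_size)) min_cluster_size <- default_min_cluster_size(n)
  if (n < 2 * min_cluster_size) {
    stop("too_few_points: need at least 2 * min_cluster_size = ",
         2 * min_cluster_size, " points, got ", n, call. = FALSE)
  }
  D <- as.matrix(stats::dist(X))
  k <- max(1L, min(as.integer(min_samples), n - 1L))
  core <- apply(D, 1, function(r) sort(r, partial = k + 1)[k + 1])
  mr <- pmax(D, matrix(core, n, n), matrix(core, n, n, byrow = TRUE))
  tree <- single_linkage_tree(mst_prim(mr), n)

  # ---- condense the tree ---------------------------------------------------
  mcs <- min_cluster_size
  clusters <- list()   # per cluster: birth_w, death_w, parent, children,
                       # points (birth leaf set), fallout_w per point
  new_cluster <- function(birth_w, parent, points) {
    clusters[[length(clusters) + 1]] <<- list(
      birth_w = birth_w, death_w = NA_real_, parent = parent,
      children = integer(0), points = points,
      fall_pts = integer(0), fall_w = numeric(0))
    length(clusters)
  }
  fallout <- function(cl, pts, w) {
    clusters[[cl]]$fall_pts <<- c(clusters[[cl]]$fall_pts, pts)
    clusters[[cl]]$fall_w <<- c(clusters[[cl]]$fall_w, rep(w, length(pts)))
  }
  root_node <- n + (n - 1)
  root_cl <- new_cluster(tree$height[n - 1], 0L, tree$leaves[[root_node]])
  stack <- list(c(node = root_node, cl = root_cl))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[["node"]]; cl <- top[["cl"]]
    if (node <= n) next  # single point, already shed by parent
    e <- node - n
    l <- tree$left[e]; r <- tree$right[e]; w <- tree$height[e]
    big_l <- tree$size[l] >= mcs
    big_r <- tree$size[r] >= mcs
    if (big_l && big_r) {
      clusters[[cl]]$death_w <- w
      cl_l <- new_cluster(w, cl, tree$leaves[[l]])
      cl_r <- new_cluster(w, cl, tree$leaves[[r]])
      clusters[[cl]]$children <- c(cl_l, cl_r)
      stack[[length(stack) + 1]] <- c(node = l, cl = cl_l)
      stack[[length(stack) + 1]] <- c(node = r, cl = cl_r)
    } else if (big_l || big_r) {
      small <- if (big_l) r else l
      big <- if (big_l) l else r
      fallout(cl, tree$leaves[[small]], w)
      stack[[length(stack) + 1]] <- c(node = big, cl = cl)
    } else {
      fallout(cl, tree$leaves[[node]], w)
    }
  }

  # ---- stability and excess-of-mass selection ------------------------------
  n_cl <- length(clusters)
  stability <- numeric(n_cl)
  for (i in seq_len(n_cl)) {
    c_i <- clusters[[i]]
    lb <- inv_lambda(c_i$birth_w)
    s <- sum(inv_lambda(c_i$fall_w) - lb)
    if (length(c_i$children)) {
      passed <- sum(vapply(c_i$children,
                           function(j) length(clusters[[j]]$points),
                           integer(1)))
      s <- s + passed * (inv_lambda(c_i$death_w) - lb)
    }
    stability[i] <- s
  }
  selected <- logical(n_cl)
  cand_stab <- numeric(n_cl)
  descendants <- function(i) {
    out <- integer(0); queue <- clusters[[i]]$children
    while (length(queue)) {
      out <- c(out, queue)
      queue <- unlist(lapply(queue, function(j) clusters[[j]]$children))
    }
    out
  }
  for (i in seq(n_cl, 1)) {
    kids <- clusters[[i]]$children
    if (!length(kids)) {
      cand_stab[i] <- stability[i]
      selected[i] <- (i != root_cl || allow_single_cluster)
    } else {
      child_sum <- sum(cand_stab[kids])
      if (stability[i] >= child_sum &&
          (i != root_cl || allow_single_cluster)) {
        selected[i] <- TRUE
        selected[descendants(i)] <- FALSE
        cand_stab[i] <- stability[i]
      } else {
        cand_stab[i] <- child_sum
      }
    }
  }
  # epsilon merging: undo selections born below the distance threshold
  if (cluster_selection_epsilon > 0) {
    repeat {
      shallow <- which(selected &
                       vapply(clusters, `[[`, numeric(1), "birth_w") <
                         cluster_selection_epsilon)
      shallow <- shallow[vapply(shallow, function(i)
        clusters[[i]]$parent != 0 &&
        (clusters[[i]]$parent != root_cl || allow_single_cluster),
        logical(1))]
      if (!length(shallow)) break
      p <- clusters[[shallow[1]]]$parent
      selected[p] <- TRUE
      selected[descendants(p)] <- FALSE
    }
  }
  if (!any(selected)) selected[root_cl] <- TRUE  # degenerate fallback

  # ---- labels, exemplars, soft membership ----------------------------------
  sel <- which(selected)
  K <- length(sel)
  labels <- integer(n)            # 0 = noise
  for (j in seq_len(K)) labels[clusters[[sel[j]]]$points] <- j
  is_noise <- labels == 0L

  # each point's final shedding height (over the whole condensed tree)
  w_out <- numeric(n)
  for (i in seq_len(n_cl)) w_out[clusters[[i]]$fall_pts] <- clusters[[i]]$fall_w

  exemplars <- lapply(seq_len(K), function(j) {
    pts <- clusters[[sel[j]]]$points
    m <- max(5L, ceiling(0.05 * length(pts)))
    pts[order(w_out[pts])[seq_len(min(m, length(pts)))]]
  })
  dist_w <- matrix(0, n, K)
  for (j in seq_len(K)) {
    dmin <- apply(D[, exemplars[[j]], drop = FALSE], 1, min)
    dist_w[, j] <- 1 / (dmin + 1e-12)
  }
  dist_w <- dist_w / rowSums(dist_w)
  membership <- dist_w * (1 - label_weight)
  idx <- cbind(which(!is_noise), labels[!is_noise])
  membership[!is_noise, ] <- membership[!is_noise, , drop = FALSE]
  membership[idx] <- membership[idx] + label_weight
  membership[is_noise, ] <- dist_w[is_noise, , drop = FALSE]
  membership <- membership / rowSums(membership)

  structure(list(
    labels = labels, membership = membership, is_noise = is_noise,
    n_clusters = K, exemplars = exemplars,
    probabilities = membership[cbind(seq_len(n),
                                     pmax(labels, 1L))] * !is_noise,
    params = list(min_samples = min_samples,
                  min_cluster_size = min_cluster_size,
                  cluster_selection_epsilon = cluster_selection_epsilon,
                  allow_single_cluster = allow_single_cluster,
                  label_weight = label_weight),
    stability = stability[sel]
  ), class = "mint_hdbscan")
}

#' @export
print.mint_hdbscan <- function(x, ...) {
  cat("HDBSCAN-style soft clustering:", x$n_clusters, "clusters,",
      sum(x$is_noise), "noise points of", length(x$labels), "\n")
  invisible(x)
}
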