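# Hierarchical density-based clustering (HDBSCAN), implemented from the
# standard construction: core distances -> mutual-reachability minimum
# spanning tree -> single-linkage hierarchy -> condensed tree (minimum
# cluster size) -> excess-of-mass cluster selection. Points not absorbed by
# any selected cluster are labeled noise.

#' Density-based clustering with noise (HDBSCAN)
#'
#' @param x Numeric matrix or data frame of observations (rows).
#' @param min_cluster_size Smallest group treated as a cluster (`>= 2`).
#' @param min_samples Neighborhood size for core distances; defaults to
#'   `min_cluster_size` (the conventional default).
#' @param allow_single_cluster If `TRUE` (default here), a dataset whose
#'   hierarchy never truly splits is returned as one cluster with no noise
#'   rather than all-noise.
#' @return A list with `labels` (integer, `NA` = noise), `n_clusters`, and
#'   the per-cluster stabilities.
#' @export
hdbscan <- function(x, min_cluster_size = 10, min_samples = min_cluster_size,
                    allow_single_cluster = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  stop_if_not(min_cluster_size >= 2, "min_cluster_size must be >= 2")
  stop_if_not(n >= 2, "too few rows")
  if (n < min_cluster_size) {
    # no group can reach the minimum cluster size: everything is noise
    return(list(labels = rep(NA_integer_, n), n_clusters = 0L,
                stability = numeric(0), selected = integer(0)))
  }

  d <- as.matrix(dist(x))
  # core distance: distance to the min_samples-th nearest neighbor,
  # counting the point itself as its first neighbor
  core <- apply(d, 1L, function(r) sort(r)[min(min_samples, n)])
  mreach <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))

  mst <- prim_mst(mreach)
  hier <- single_linkage(mst, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  select_eom(cond, n, allow_single_cluster)
}

# dense-matrix Prim; returns edges (from, to, weight), n-1 rows
prim_mst <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  d_to <- w[1, ]
  parent <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n - 1L)) {
    d_masked <- ifelse(in_tree, Inf, d_to)
    j <- which.min(d_masked)
    edges[k, ] <- c(parent[j], j, d_to[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < d_to
    parent[upd] <- j
    d_to[upd] <- w[j, upd]
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# single-linkage dendrogram over sorted MST edges; nodes 1..n are points,
# nodes n+1..2n-1 merges. Returns per-merge children, height, and the point
# sets of every internal node.
single_linkage <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  n_nodes <- 2L * n - 1L
  left <- right <- integer(n_nodes)
  height <- numeric(n_nodes)
  points <- vector("list", n_nodes)
  points[seq_len(n)] <- as.list(seq_len(n))
  nxt <- n
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    nxt <- nxt + 1L
    left[nxt] <- ra; right[nxt] <- rb; height[nxt] <- edges[k, 3]
    points[[nxt]] <- c(points[[ra]], points[[rb]])
    parent[ra] <- nxt; parent[rb] <- nxt
  }
  list(left = left, right = right, height = height, points = points,
       root = n_nodes)
}

# walk the dendrogram top-down, condensing it: merges where both sides hold
# at least min_cluster_size points are true splits (new clusters); smaller
# side(s) fall out of the current cluster as candidate noise at that level's
# lambda = 1 / distance
condense_tree <- function(hier, n, mcs) {
  sizes <- lengths(hier$points)
  clusters <- list()  # per cluster: lambda_birth, parent, children, stability
  new_cluster <- function(parent, lambda_birth) {
    id <- length(clusters) + 1L
    clusters[[id]] <<- list(id = id, parent = parent,
                            lambda_birth = lambda_birth,
                            children = integer(0), stability = 0,
                            points = integer(0), point_lambda = numeric(0))
    id
  }
  lam <- function(h) 1 / max(h, 1e-12)

  root_id <- new_cluster(0L, lam(hier$height[hier$root]))
  # point chain membership: we record, per point, the cluster in which it
  # finally fell out; ancestors are recovered via parent links
  fell_in <- integer(n)

  stack <- list(list(node = hier$root, cl = root_id))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node; cl <- top$cl
    if (node <= n) { # singleton passed down (only possible with mcs = 1)
      clusters[[cl]]$points <- c(clusters[[cl]]$points, node)
      clusters[[cl]]$point_lambda <- c(clusters[[cl]]$point_lambda, Inf)
      fell_in[node] <- cl
      next
    }
    l <- hier$left[node]; r <- hier$right[node]
    lv <- lam(hier$height[node])
    sl <- sizes[l]; sr <- sizes[r]
    if (sl >= mcs && sr >= mcs) {
      for (child in c(l, r)) {
        cid <- new_cluster(cl, lv)
        clusters[[cl]]$children <- c(clusters[[cl]]$children, cid)
        stack[[length(stack) + 1L]] <- list(node = child, cl = cid)
      }
      # points passing into children leave the parent at lv
      clusters[[cl]]$stability <- clusters[[cl]]$stability +
        (sl + sr) * clamp_lambda(lv - clusters[[cl]]$lambda_birth)
    } else {
      big <- if (sl >= mcs) l else if (sr >= mcs) r else NA_integer_
      small <- setdiff(c(l, r), big)
      for (s in small) {
        pts <- hier$points[[s]]
        clusters[[cl]]$points <- c(clusters[[cl]]$points, pts)
        clusters[[cl]]$point_lambda <- c(clusters[[cl]]$point_lambda,
                                         rep(lv, length(pts)))
        fell_in[pts] <- cl
        clusters[[cl]]$stability <- clusters[[cl]]$stability +
          length(pts) * clamp_lambda(lv - clusters[[cl]]$lambda_birth)
      }
      if (!is.na(big)) {
        stack[[length(stack) + 1L]] <- list(node = big, cl = cl)
      }
    }
  }
  list(clusters = clusters, fell_in = fell_in, root = root_id)
}

clamp_lambda <- function(x) {
  x[!is.finite(x)] <- 0
  pmax(x, 0)
}

# excess-of-mass selection over the condensed tree
select_eom <- function(cond, n, allow_single_cluster) {
  cl <- cond$clusters
  k <- length(cl)
  sel <- logical(k)
  sel_stab <- numeric(k)
  # children always have larger ids than parents: reverse id order is a
  # valid bottom-up traversal
  for (id in rev(seq_len(k))) {
    ch <- cl[[id]]$children
    if (length(ch) == 0) {
      sel[id] <- TRUE
      sel_stab[id] <- cl[[id]]$stability
    } else {
      child_sum <- sum(sel_stab[ch])
      is_root <- id == cond$root
      if (child_sum > cl[[id]]$stability || (is_root && !allow_single_cluster)) {
        sel_stab[id] <- child_sum
      } else {
        sel[id] <- TRUE
        sel_stab[id] <- cl[[id]]$stability
        # deselect entire subtree below
        queue <- ch
        while (length(queue) > 0) {
          q <- queue[[1]]; queue <- queue[-1]
          sel[q] <- FALSE
          queue <- c(queue, cl[[q]]$children)
        }
      }
    }
  }
  # root is only kept when it never split (single-cluster data)
  if (sel[cond$root] && length(cl[[cond$root]]$children) > 0 &&
      sum(sel) > 1) {
    sel[cond$root] <- FALSE
  }
  labels <- rep(NA_integer_, n)
  if (any(sel)) {
    sel_ids <- which(sel)
    for (p in seq_len(n)) {
      c_id <- cond$fell_in[p]
      while (c_id != 0L && !(c_id %in% sel_ids)) c_id <- cl[[c_id]]$parent
      if (c_id != 0L) labels[p] <- c_id
    }
    # single-cluster fallback: when the root itself is the selected cluster,
    # everything belongs to it
    if (identical(sel_ids, cond$root)) labels[] <- cond$root
    labels <- as.integer(factor(labels, levels = sel_ids))
  }
  list(labels = labels,
       n_clusters = length(unique(labels[!is.na(labels)])),
       stability = vapply(cl, function(z) z$stability, numeric(1)),
       selected = which(sel))
}
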