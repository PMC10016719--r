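#' PCA reduction retaining a fixed fraction of variance
#'
#' Principal component analysis of a complete, standardized feature matrix,
#' retaining the smallest number of leading components whose cumulative
#' explained-variance fraction reaches `variance_threshold`.
#'
#' @param matrix Data frame or matrix; non-numeric columns (identifiers) are
#'   carried through to the score tibble unchanged.
#' @param variance_threshold Fraction of variance to retain (default 0.95).
#' @return A list with `model` (a `pca_model`: loadings, explained-variance
#'   fractions, `n_retained`) and `scores` (tibble of retained component
#'   scores `PC1..PCn` plus any identifier columns).
#' @export
pca_reduce <- function(matrix, variance_threshold = 0.95) {
  stop_if_not(is.data.frame(matrix) || is.matrix(matrix),
              "matrix must be a data frame or matrix")
  df <- as_tibble(as.data.frame(matrix))
  num <- vapply(df, is.numeric, logical(1))
  x <- as.matrix(df[num])
  stop_if_not(nrow(x) >= 2, "need at least 2 rows")
  keep_var <- apply(x, 2, var) > 0
  p <- prcomp(x[, keep_var, drop = FALSE], center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  n_ret <- which(cumsum(frac) >= variance_threshold - 1e-12)[1]
  scores <- as_tibble(as.data.frame(p$x[, seq_len(n_ret), drop = FALSE]))
  model <- structure(
    list(loadings = p$rotation[, seq_len(n_ret), drop = FALSE],
         center = p$center,
         explained_variance_fractions = frac,
         n_retained = n_ret,
         variance_threshold = variance_threshold),
    class = "pca_model")
  list(model = model,
       scores = dplyr::bind_cols(df[!num], scores))
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "PCA model: %d of %d components retained (>= %.0f%% variance; %.1f%% kept)\n",
    x$n_retained, length(x$explained_variance_fractions),
    100 * x$variance_threshold,
    100 * sum(x$explained_variance_fractions[seq_len(x$n_retained)])))
  invisible(x)
}

score_columns <- function(df) {
  df[vapply(df, is.numeric, logical(1)) & grepl("^PC", names(df))]
}

numeric_matrix <- function(df) {
  if (is.matrix(df)) return(df)
  sc <- score_columns(df)
  if (ncol(sc) > 0) return(as.matrix(sc))
  as.matrix(df[vapply(df, is.numeric, logical(1))])
}

#' Density-based clustering of PCA scores with a noise flag
#'
#' Runs HDBSCAN (see [hdbscan()]) on the score matrix. Points not belonging
#' to any sufficiently dense region are flagged as noise; downstream they are
#' reassigned to the nearest cluster center by [assign_noise()].
#'
#' @param scores Data frame of PCA scores (or any numeric matrix).
#' @param min_cluster_size Minimum cluster size (default 10).
#' @return Tibble with columns `cluster` (integer, `NA` for noise) and
#'   `noise` (logical).
#' @export
cluster_density <- function(scores, min_cluster_size = 10) {
  x <- numeric_matrix(scores)
  res <- hdbscan(x, min_cluster_size = min_cluster_size)
  tibble(cluster = res$labels, noise = is.na(res$labels))
}

#' K-means with silhouette-based selection of the cluster count
#'
#' Runs seeded K-means for each `k` in `k_range` and keeps the `k` with the
#' largest mean silhouette width.
#'
#' @param scores Data frame of PCA scores or numeric matrix (> 10 rows).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Seed for the K-means initializations.
#' @param nstart Random restarts per `k`.
#' @return List: `labels` (integer), `chosen_k`, `silhouette_by_k` (tibble
#'   `k`, `mean_silhouette`).
#' @export
cluster_kmeans_silhouette <- function(scores, k_range = 2:10, seed = 42,
                                      nstart = 10) {
  x <- numeric_matrix(scores)
  stop_if_not(nrow(x) > 10, "need more than 10 rows")
  stop_if_not(nrow(unique(x)) > 1, "degenerate data: all rows identical")
  k_range <- k_range[k_range < nrow(x)]
  dmat <- dist(x)
  fits <- with_seed(seed, lapply(k_range, function(k) {
    km <- kmeans(x, centers = k, nstart = nstart, iter.max = 100)
    sil <- cluster::silhouette(km$cluster, dmat)
    list(km = km, mean_sil = mean(sil[, "sil_width"]))
  }))
  sil_by_k <- tibble(k = k_range,
                     mean_silhouette = vapply(fits, `[[`, numeric(1),
                                              "mean_sil"))
  best <- which.max(sil_by_k$mean_silhouette)
  list(labels = fits[[best]]$km$cluster,
       chosen_k = k_range[best],
       silhouette_by_k = sil_by_k)
}

#' Assign noise points to the nearest cluster center
#'
#' Each noise point receives the label of the cluster whose geometric center
#' (arithmetic mean of member scores) is closest in Euclidean distance; ties
#' go to the lowest cluster index.
#'
#' @param noise_points Numeric matrix / data frame of noise-point scores.
#' @param centers Numeric matrix of cluster centers (one row per cluster, in
#'   cluster-index order).
#' @return Integer vector of cluster labels (empty when there are no noise
#'   points).
#' @export
assign_noise <- function(noise_points, centers) {
  centers <- as.matrix(centers)
  stop_if_not(nrow(centers) >= 1, "empty centers")
  x <- numeric_matrix(noise_points)
  if (nrow(x) == 0) return(integer(0))
  apply(x, 1, function(p) {
    d2 <- colSums((t(centers) - p)^2)
    which.min(d2)  # which.min takes the first (lowest index) on ties
  })
}

cluster_centers <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels[!is.na(labels)]))
  t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
           numeric(ncol(x))))
}

# density clustering + noise reassignment on a fresh PCA of `feats`
density_level <- function(feats, variance_threshold, min_cluster_size) {
  red <- pca_reduce(feats, variance_threshold)
  sc <- as.matrix(score_columns(red$scores))
  dens <- cluster_density(sc, min_cluster_size)
  labels <- dens$cluster
  if (all(is.na(labels))) labels <- rep(1L, nrow(sc))
  if (anyNA(labels)) {
    ctr <- cluster_centers(sc, labels)
    labels[is.na(labels)] <- assign_noise(sc[is.na(labels), , drop = FALSE],
                                          ctr)
  }
  list(labels = as.integer(labels), pca = red$model, scores = sc,
       centers = cluster_centers(sc, labels), noise = dens$noise)
}

#' Nested three-level dimensionality reduction and clustering
#'
#' Level 1 applies density clustering (HDBSCAN, noise reassigned to nearest
#' centers) to the PCA scores of all models. Level 2 re-fits PCA on the
#' members of the designated level-1 cluster (by default the largest) and
#' repeats the density clustering. Level 3 re-fits PCA on the designated
#' level-2 cluster and applies silhouette-selected K-means. PCA is refit at
#' every level so each level's scores reflect within-subset variation.
#' Recursion stops early when a level finds a single cluster.
#'
#' @param matrix Complete standardized feature matrix (data frame; numeric
#'   columns are clustered, an optional `model_id` column identifies rows).
#' @param variance_threshold PCA explained-variance threshold per level.
#' @param min_cluster_size HDBSCAN minimum cluster size (levels 1-2).
#' @param k_range K-means candidate cluster counts (level 3).
#' @param seed Seed for K-means.
#' @param recurse_into Optional `c(level1_cluster, level2_cluster)` override
#'   of which cluster is recursed into; `NA` entries mean "the largest".
#' @return A `cluster_tree` object: `$assignments` tibble (`model_id`,
#'   `level1`, `level2`, `level3`, `final_label`, `level1_noise`), plus the
#'   per-level PCA models, centers and silhouette profile.
#' @export
run_nested_clustering <- function(matrix, variance_threshold = 0.95,
                                  min_cluster_size = 10, k_range = 2:10,
                                  seed = 42, recurse_into = c(NA, NA)) {
  df <- as_tibble(as.data.frame(matrix))
  ids <- if ("model_id" %in% names(df)) df$model_id else
    paste0("model_", seq_len(nrow(df)))
  feats <- df[vapply(df, is.numeric, logical(1))]

  pick <- function(labels, override) {
    if (!is.na(override)) return(as.integer(override))
    tab <- table(labels)
    as.integer(names(tab)[which.max(tab)])
  }

  l1 <- density_level(feats, variance_threshold, min_cluster_size)
  level1 <- l1$labels
  level2 <- rep(NA_integer_, nrow(df))
  level3 <- rep(NA_integer_, nrow(df))
  l2 <- l3 <- NULL
  target1 <- target2 <- NA_integer_

  if (length(unique(level1)) >= 2) {
    target1 <- pick(level1, recurse_into[1])
    in1 <- level1 == target1
    if (sum(in1) >= max(min_cluster_size, 2)) {
      l2 <- density_level(feats[in1, , drop = FALSE], variance_threshold,
                          min_cluster_size)
      level2[in1] <- l2$labels
      if (length(unique(l2$labels)) >= 2) {
        target2 <- pick(level2[in1], recurse_into[2])
        in2 <- in1 & !is.na(level2) & level2 == target2
        if (sum(in2) > 10) {
          red3 <- pca_reduce(feats[in2, , drop = FALSE], variance_threshold)
          l3 <- cluster_kmeans_silhouette(red3$scores, k_range = k_range,
                                          seed = seed)
          l3$pca <- red3$model
          level3[in2] <- l3$labels
        }
      }
    }
  }

  final <- dplyr::case_when(
    !is.na(level3) ~ paste0("L3-", level3),
    !is.na(level2) & (is.na(target2) | level2 != target2) ~
      paste0("L2-", level2),
    !is.na(level2) ~ paste0("L2-", level2),
    is.na(target1) | level1 != target1 ~ paste0("L1-", level1),
    TRUE ~ paste0("L1-", level1)
  )

  structure(
    list(assignments = tibble(model_id = ids, level1 = level1,
                              level2 = level2, level3 = level3,
                              final_label = final,
                              level1_noise = l1$noise),
         level1 = l1, level2 = l2, level3 = l3,
         recursed_into = c(target1, target2)),
    class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  a <- x$assignments
  cat("Nested cluster tree\n")
  cat("  level 1:", length(unique(a$level1)), "clusters over",
      nrow(a), "models\n")
  if (!all(is.na(a$level2)))
    cat("  level 2:", length(unique(a$level2[!is.na(a$level2)])),
        "clusters in level-1 cluster", x$recursed_into[1], "\n")
  if (!all(is.na(a$level3)))
    cat("  level 3:", length(unique(a$level3[!is.na(a$level3)])),
        "K-means clusters in level-2 cluster", x$recursed_into[2], "\n")
  invisible(x)
}

#' Pearson correlation between two features within one cluster
#'
#' @param data Data frame restricted to the members of one cluster.
#' @param feature_a,feature_b Column names.
#' @return One-row tibble `r`, `p_value`, `n`.
#' @export
correlate_within_cluster <- function(data, feature_a, feature_b) {
  stop_if_not(nrow(data) >= 3, "need >= 3 cluster members")
  a <- data[[feature_a]]
  b <- data[[feature_b]]
  stop_if_not(sd(a) > 0 && sd(b) > 0, "zero variance in a feature")
  ct <- cor.test(a, b, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(data))
}

#' Attach interpretive labels to cluster assignments
#'
#' Cluster names such as "non-positive rheobase" or "abstract spiker" are
#' post-hoc interpretations; this helper renames final labels via an
#' explicit rule table rather than learning them.
#'
#' @param tree A `cluster_tree`.
#' @param rules Tibble with columns `final_label`, `label`.
#' @return The assignments tibble with a `label` column.
#' @export
attach_cluster_labels <- function(tree, rules) {
  dplyr::left_join(tree$assignments, rules, by = "final_label")
}
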