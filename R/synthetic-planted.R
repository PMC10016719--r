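#' Planted Gaussian cluster matrix
#'
#' Draws `k` spherical Gaussian components (unit within-cluster standard
#' deviation) whose centers are pairwise separated by `separation` standard
#' deviations, and returns the matrix together with the true labels. Used to
#' validate the clustering stages against known structure.
#'
#' @param k Number of components (`>= 1`).
#' @param n_per_cluster Points per component (`>= 1`).
#' @param separation Pairwise center distance in within-cluster standard
#'   deviations.
#' @param n_features Dimensionality (`>= k` for the center construction).
#' @param seed Integer seed.
#' @return List: `matrix` (tibble with `model_id` and `V1..Vd`), `labels`
#'   (integer vector of true components).
#' @export
generate_planted_feature_matrix <- function(k, n_per_cluster, separation = 8,
                                            n_features = max(4, k),
                                            seed = 1L) {
  stop_if_not(k >= 1 && n_per_cluster >= 1, "k and n_per_cluster must be >= 1")
  stop_if_not(n_features >= k, "need n_features >= k")
  # centers on scaled unit axes: pairwise distance = separation
  centers <- diag(n_features)[seq_len(k), , drop = FALSE] *
    separation / sqrt(2)
  labels <- rep(seq_len(k), each = n_per_cluster)
  x <- with_seed(seed, {
    centers[labels, , drop = FALSE] +
      matrix(rnorm(length(labels) * n_features), ncol = n_features)
  })
  colnames(x) <- paste0("V", seq_len(n_features))
  list(matrix = dplyr::bind_cols(
         tibble(model_id = sprintf("model_%03d", seq_along(labels))),
         as_tibble(as.data.frame(x))),
       labels = labels)
}

#' Planted three-level cluster hierarchy
#'
#' Generates a feature matrix with nested structure mirroring how nested
#' cell-type structure appears in real characterizations: each level's
#' separation lives in its own feature subspace, and the variance scale of
#' deeper levels decreases geometrically, so that a PCA retaining 95% of
#' variance on the full data sees only the top-level structure, a PCA refit
#' on the largest top-level cluster sees only the second level, and so on.
#'
#' Defaults plant `sizes = c(4, 2, 6)`: four top-level clusters; the largest
#' splits in two; the larger of those splits into six. Within-cluster noise
#' has unit standard deviation in every one of the 8 dimensions, and
#' `separation` is the minimum center separation (in noise SDs) at the level
#' where each split is clustered.
#'
#' @param n_leaf Points per leaf cluster at the deepest level.
#' @param separation Minimum center separation in within-cluster SDs.
#' @param seed Integer seed.
#' @return List: `matrix` (tibble), `labels` (tibble `model_id`, `level1`,
#'   `level2`, `level3`; deeper labels are `NA` outside the recursed path).
#' @export
generate_planted_hierarchy <- function(n_leaf = 30, separation = 8,
                                       seed = 1L) {
  d <- 8L
  s1 <- separation * 25   # level-1 scale dominates global variance
  s2 <- separation * 8    # level-2 scale dominates within-cluster-1 variance
  s3 <- separation        # level-3 scale, resolved by K-means

  c1 <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)) * s1 / 2  # dims 1:2
  hex <- s3 * cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))

  n1 <- c(11L * n_leaf, 3L * n_leaf, 3L * n_leaf, 3L * n_leaf)
  rows <- list()
  lab <- list()
  for (g in 1:4) {
    m <- matrix(0, n1[g], d)
    m[, 1:2] <- matrix(c1[g, ], n1[g], 2, byrow = TRUE)
    l2 <- rep(NA_integer_, n1[g])
    l3 <- rep(NA_integer_, n1[g])
    if (g == 1) {
      # split 6*n_leaf vs 5*n_leaf along dim 3
      l2 <- rep(c(1L, 2L), c(6L * n_leaf, 5L * n_leaf))
      m[, 3] <- ifelse(l2 == 1L, -s2 / 2, s2 / 2)
      # six leaves inside sub-cluster 1, hexagon in dims 4:5
      l3[l2 == 1L] <- rep(1:6, each = n_leaf)
      m[l2 == 1L, 4:5] <- hex[l3[l2 == 1L], ]
    }
    rows[[g]] <- m
    lab[[g]] <- tibble(level1 = g, level2 = l2, level3 = l3)
  }
  m <- do.call(rbind, rows)
  labels <- dplyr::bind_rows(lab)
  x <- with_seed(seed, m + matrix(rnorm(length(m)), ncol = d))
  colnames(x) <- paste0("V", seq_len(d))
  ids <- sprintf("model_%04d", seq_len(nrow(x)))
  list(matrix = dplyr::bind_cols(tibble(model_id = ids),
                                 as_tibble(as.data.frame(x))),
       labels = dplyr::bind_cols(tibble(model_id = ids), labels))
}
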