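test_that("pca_reduce keeps the smallest component count reaching the threshold", {
  set.seed(4)
  one_axis <- tibble::tibble(a = rnorm(100), b = 0, c = 0)
  expect_equal(pca_reduce(suppressWarnings(one_axis))$model$n_retained, 1)

  iso <- as.data.frame(matrix(rnorm(4000 * 3), ncol = 3))
  # oracle: eigenvalues of the sample covariance determine the count
  ev <- sort(eigen(cov(as.matrix(iso)))$values, decreasing = TRUE)
  expected <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(expected, 3)
  expect_equal(pca_reduce(iso)$model$n_retained, expected)

  set.seed(5)
  any_data <- as.data.frame(matrix(rnorm(50 * 8), ncol = 8))
  mod <- pca_reduce(any_data)$model
  expect_gte(sum(mod$explained_variance_fractions[seq_len(mod$n_retained)]),
             0.95)
  expect_error(pca_reduce(any_data[1, ]), "2 rows")
})

test_that("density clustering separates planted blobs and flags sparse data", {
  g <- generate_planted_feature_matrix(2, 50, separation = 10, seed = 1)
  cd <- cluster_density(g$matrix, min_cluster_size = 10)
  expect_equal(length(unique(cd$cluster[!cd$noise])), 2)
  expect_equal(ari(cd$cluster, g$labels), 1.0)

  tiny <- generate_planted_feature_matrix(1, 5, seed = 2)
  cd_tiny <- cluster_density(tiny$matrix, min_cluster_size = 10)
  expect_true(all(cd_tiny$noise))

  blob <- generate_planted_feature_matrix(1, 100, seed = 3)
  cd_blob <- cluster_density(blob$matrix, min_cluster_size = 10)
  expect_equal(unique(cd_blob$cluster), 1L)
  expect_false(any(cd_blob$noise))
})

test_that("silhouette-selected K-means matches a first-principles oracle", {
  for (k_true in 2:3) {
    g <- generate_planted_feature_matrix(k_true, 40, separation = 10,
                                         seed = 10 + k_true)
    x <- as.matrix(g$matrix[, -1])
    res <- cluster_kmeans_silhouette(x)
    expect_equal(res$chosen_k, k_true)
    expect_equal(res$chosen_k, choose_k_oracle(x))
    expect_equal(ari(res$labels, g$labels), 1.0)
  }
  same <- matrix(1, 20, 3)
  expect_error(cluster_kmeans_silhouette(same), "degenerate")
})

test_that("noise points go to the nearest center, ties to the lowest index", {
  centers <- rbind(c(0, 0), c(10, 0))
  expect_equal(assign_noise(rbind(c(0, 0)), centers), 1L)
  expect_equal(assign_noise(rbind(c(10, 0.5)), centers), 2L)
  expect_equal(assign_noise(rbind(c(5, 0)), centers), 1L)  # equidistant
  expect_length(assign_noise(matrix(numeric(0), ncol = 2), centers), 0)
  expect_error(assign_noise(rbind(c(1, 1)), centers[0, ]), "empty centers")
})

test_that("nested clustering recovers a planted 4 -> 2 -> 6 hierarchy", {
  h <- generate_planted_hierarchy(n_leaf = 30, separation = 8, seed = 2)
  tree <- run_nested_clustering(h$matrix)
  a <- dplyr::left_join(tree$assignments, h$labels, by = "model_id",
                        suffix = c("", "_true"))
  expect_equal(length(unique(a$level1)), 4)
  expect_gte(ari(a$level1, a$level1_true), 0.9)
  l2 <- a[!is.na(a$level2_true), ]
  expect_equal(length(unique(l2$level2[!is.na(l2$level2)])), 2)
  expect_gte(ari(l2$level2, l2$level2_true), 0.9)
  l3 <- a[!is.na(a$level3_true), ]
  expect_equal(length(unique(l3$level3[!is.na(l3$level3)])), 6)
  expect_gte(ari(l3$level3, l3$level3_true), 0.9)
  # every model ends in a leaf cluster
  expect_false(any(is.na(a$final_label)))
})

test_that("recursion stops on a single homogeneous cluster", {
  g <- generate_planted_feature_matrix(1, 60, seed = 4)
  tree <- run_nested_clustering(g$matrix)
  expect_equal(unique(tree$assignments$level1), 1L)
  expect_true(all(is.na(tree$assignments$level2)))
  expect_true(all(is.na(tree$assignments$level3)))
})

test_that("each level refits PCA on its subset rather than slicing scores", {
  h <- generate_planted_hierarchy(n_leaf = 25, separation = 8, seed = 3)
  tree <- run_nested_clustering(h$matrix)
  in1 <- tree$assignments$level1 == tree$recursed_into[1]
  feats <- h$matrix[, -1]
  refit <- pca_reduce(feats[in1, ])
  sliced <- tree$level1$scores[in1, , drop = FALSE]
  # the subset PCA sees within-cluster structure the global PCA discarded:
  # its leading component is far wider than anything in the sliced scores
  refit_sd <- apply(as.matrix(refit$scores), 2, sd)
  expect_gt(max(refit_sd), 3 * max(apply(sliced, 2, sd)))
})

test_that("the top loading of component 1 identifies the dominant feature", {
  set.seed(8)
  m <- tibble::tibble(delay = rnorm(80, sd = 10), a = rnorm(80), b = rnorm(80))
  mod <- pca_reduce(m)$model
  top <- rownames(mod$loadings)[which.max(abs(mod$loadings[, 1]))]
  expect_identical(top, "delay")
})

test_that("within-cluster correlations match the closed-form cases", {
  col <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(correlate_within_cluster(col, "x", "y")$r, 1, tolerance = 1e-12)
  anti <- tibble::tibble(x = c(1, 2, 3), y = c(6, 4, 2))
  expect_equal(correlate_within_cluster(anti, "x", "y")$r, -1,
               tolerance = 1e-12)
  set.seed(11)
  ind <- tibble::tibble(x = rnorm(2000), y = rnorm(2000))
  expect_lt(abs(correlate_within_cluster(ind, "x", "y")$r), 0.1)
  expect_error(correlate_within_cluster(col[1:2, ], "x", "y"), "3")
  flat <- tibble::tibble(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(correlate_within_cluster(flat, "x", "y"), "variance")
})
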