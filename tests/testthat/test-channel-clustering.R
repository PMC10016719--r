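make_family_responses <- function(specs, grid_points = 64) {
  resp <- generate_channel_response_set(specs)
  lapply(stats::setNames(nm = c("activation", "deactivation", "inactivation")),
         function(p) condense_responses(resp, p, grid_points = grid_points))
}

test_that("condensation is deterministic, zero-preserving and rate-invariant", {
  specs <- list(a = channel_family_spec("Kv"), b = channel_family_spec("Kv"))
  resp <- generate_channel_response_set(specs)
  cm <- condense_responses(resp, "activation", grid_points = 64)
  expect_equal(cm["a", ], cm["b", ], tolerance = 1e-12)

  zero <- resp
  zero$current <- 0
  cz <- condense_responses(zero, "activation", grid_points = 64)
  expect_true(all(cz == 0))

  # the same model sampled at twice the rate condenses to the same row
  pr1 <- standard_clamp_protocols(sampling_interval_ms = 0.2)
  pr2 <- standard_clamp_protocols(sampling_interval_ms = 0.1)
  r1 <- generate_channel_response_set(specs["a"], pr1)
  r2 <- generate_channel_response_set(specs["a"], pr2)
  c1 <- condense_responses(r1, "activation", grid_points = 64)
  c2 <- condense_responses(r2, "activation", grid_points = 64)
  expect_equal(c1, c2, tolerance = 1e-3)

  bad <- resp
  bad$step_mv[bad$model_id == "b"] <- bad$step_mv[bad$model_id == "b"] + 5
  expect_error(condense_responses(bad, "activation"), "inconsistent voltage")
})

test_that("family scoring yields one 3-vector per model", {
  g <- generate_channel_archetype_set("Kv", 3, seed = 5)
  cond <- make_family_responses(g$specs)
  sc <- compute_family_scores(cond)
  expect_equal(nrow(sc), length(g$specs))
  expect_named(sc, c("model_id", "ll_activation", "ll_deactivation",
                     "ll_inactivation"))
  # identical specs receive identical score vectors
  dup <- sc[match(g$truth$model_id[g$truth$archetype == 1], sc$model_id), ]
  expect_lt(max(apply(as.matrix(dup[, -1]), 2, function(x) diff(range(x)))),
            1e-3)
  expect_error(compute_family_scores(cond[c("activation", "deactivation")]),
               "missing protocol")
})

test_that("a foreign-family response scores lower under the family model", {
  kv <- lapply(1:8, function(i) channel_family_spec("Kv"))
  names(kv) <- sprintf("kv_%d", 1:8)
  mixed <- c(kv, list(nav_1 = channel_family_spec("Nav")))
  sc <- compute_family_scores(make_family_responses(mixed))
  kv_ll <- sc$ll_activation[sc$model_id != "nav_1"]
  expect_lt(sc$ll_activation[sc$model_id == "nav_1"], min(kv_ll))
})

test_that("channel clustering separates planted groups, keeps singletons", {
  g <- generate_planted_feature_matrix(2, 8, separation = 12, seed = 1)
  cc <- cluster_channels(g$matrix)
  expect_equal(ari(cc$labels$cluster, g$labels[order(g$matrix$model_id)]), 1.0)

  set.seed(6)
  sc <- tibble::tibble(model_id = sprintf("m%02d", 1:13),
                       s1 = c(rnorm(12, sd = 0.3), 40),
                       s2 = c(rnorm(12, sd = 0.3), 40),
                       s3 = c(rnorm(12, sd = 0.3), 40))
  out <- cluster_channels(sc)
  outlier_cluster <- out$labels$cluster[out$labels$model_id == "m13"]
  expect_equal(sum(out$labels$cluster == outlier_cluster), 1)

  same <- tibble::tibble(model_id = c("a", "b", "c"), s = c(1, 1, 1))
  expect_equal(unique(cluster_channels(same)$labels$cluster), 1L)
})

test_that("permuting model order permutes cluster labels consistently", {
  g <- generate_channel_archetype_set("Kv", 3, seed = 2)
  resp1 <- generate_channel_response_set(g$specs)
  perm <- withr::with_seed(1, sample(seq_along(g$specs)))
  resp2 <- generate_channel_response_set(g$specs[perm])
  ch1 <- characterize_channels(resp1, grid_points = 64)
  ch2 <- characterize_channels(resp2, grid_points = 64)
  j <- dplyr::inner_join(ch1$clusters$labels, ch2$clusters$labels,
                         by = "model_id")
  expect_identical(j$cluster.x, j$cluster.y)
})

test_that("end-to-end channel characterization recovers kinetic archetypes", {
  g <- generate_channel_archetype_set("Kv", 3, seed = 4)
  ch <- characterize_channels(generate_channel_response_set(g$specs),
                              grid_points = 64)
  lab <- ch$clusters$labels$cluster[match(g$truth$model_id,
                                          ch$clusters$labels$model_id)]
  expect_gte(ari(lab, g$truth$archetype), 0.8)
})
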