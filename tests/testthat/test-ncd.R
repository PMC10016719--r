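test_that("somatic density parsing converts units and zeroes absent channels", {
  p <- write_test_nml(c(
    '<channelDensity id="d1" ionChannel="kv_a" condDensity="0.12 S_per_cm2" segmentGroup="soma_group"/>',
    '<channelDensity id="d2" ionChannel="nav_b" condDensity="35 mS_per_cm2" segmentGroup="soma_group"/>',
    '<channelDensity id="d3" ionChannel="cav_c" condDensity="0.2 S_per_cm2" segmentGroup="dendrite_group"/>'))
  row <- parse_somatic_densities(p, c("kv_a", "nav_b", "cav_c", "kca_d"))
  expect_equal(row$kv_a, 120)
  expect_equal(row$nav_b, 35)
  expect_equal(row$cav_c, 0)   # dendrite-only channel ignored for the soma
  expect_equal(row$kca_d, 0)   # absent channel is exactly zero
})

test_that("multiple somatic segments average and S_per_m2 converts", {
  p <- write_test_nml(c(
    '<channelDensity id="d1" ionChannel="kv_a" condDensity="100 S_per_m2" segmentGroup="soma_0"/>',
    '<channelDensity id="d2" ionChannel="kv_a" condDensity="300 S_per_m2" segmentGroup="soma_1"/>'))
  row <- parse_somatic_densities(p, "kv_a")
  expect_equal(row$kv_a, mean(c(10, 30)))
})

test_that("malformed XML and unknown units are rejected", {
  bad <- tempfile(fileext = ".nml")
  writeLines("<neuroml><unclosed>", bad)
  expect_error(parse_somatic_densities(bad, "kv_a"))
  p <- write_test_nml(
    '<channelDensity id="d" ionChannel="kv_a" condDensity="3 furlongs" segmentGroup="soma"/>')
  expect_error(parse_somatic_densities(p, "kv_a"), "unparseable")
})

test_that("max scaling maps each channel column onto [0, 1]", {
  tbl <- tibble::tibble(cell_id = c("a", "b", "c"),
                        k1 = c(2, 4, 8), k2 = c(0, 0, 0))
  sc <- normalize_densities(tbl)
  expect_equal(sc$k1, c(0.25, 0.5, 1))
  expect_equal(sc$k2, c(0, 0, 0))
  expect_true(all(vapply(sc[, -1], max, numeric(1)) %in% c(0, 1)))
  expect_error(normalize_densities(tibble::tibble(cell_id = "a", k = -1)),
               "negative")
})

test_that("NCD integration sums scaled densities over channel clusters", {
  sc <- tibble::tibble(cell_id = c("a", "b"),
                       k1 = c(0.5, 0), k2 = c(0.25, 0), k3 = c(0.9, 0))
  cl <- tibble::tibble(model_id = c("k1", "k2", "k3"), cluster = c(1, 1, 2))
  ncd <- integrate_cluster_density(sc, cl)
  expect_equal(ncd$ncd_1, c(0.75, 0))
  expect_equal(ncd$ncd_2, c(0.9, 0))  # singleton cluster = scaled value
  expect_true(all(as.matrix(ncd[2, -1]) == 0))
  expect_error(integrate_cluster_density(sc, cl[1:2, ]), "unlabeled")
})

test_that("raising a raw density never lowers the corresponding NCD", {
  set.seed(3)
  tbl <- tibble::tibble(cell_id = sprintf("c%d", 1:6),
                        k1 = runif(6), k2 = runif(6))
  cl <- tibble::tibble(model_id = c("k1", "k2"), cluster = c(1, 1))
  base_ncd <- integrate_cluster_density(normalize_densities(tbl), cl)
  bumped <- tbl
  bumped$k1[2] <- bumped$k1[2] + 0.5
  new_ncd <- integrate_cluster_density(normalize_densities(bumped), cl)
  expect_gte(new_ncd$ncd_1[2], base_ncd$ncd_1[2])
})

test_that("uniform column scaling preserves between-cell profile correlations", {
  set.seed(9)
  raw <- matrix(runif(5 * 4, 1, 9), nrow = 5)
  raw[1, ] <- 10  # common positive column max
  tbl <- dplyr::bind_cols(tibble::tibble(cell_id = sprintf("c%d", 1:5)),
                          tibble::as_tibble(as.data.frame(raw)))
  sc <- normalize_densities(tbl)
  for (pair in list(c(2, 3), c(3, 4), c(2, 5))) {
    r_raw <- cor(as.numeric(tbl[pair[1], -1]), as.numeric(tbl[pair[2], -1]))
    r_sc <- cor(as.numeric(sc[pair[1], -1]), as.numeric(sc[pair[2], -1]))
    expect_equal(r_sc, r_raw, tolerance = 1e-12)
  }
})

test_that("NCD summaries are exact for zero-variance clusters", {
  ncd <- tibble::tibble(cell_id = c("a", "b", "c"), ncd_1 = c(0.4, 0.4, 0.4))
  cl <- tibble::tibble(cell_id = c("a", "b", "c"), cluster = "X")
  s <- summarize_ncd(ncd, cl, n_boot = 200, seed = 1)
  expect_equal(s$mean_ncd, 0.4)
  expect_equal(s$ci_lo, 0.4)
  expect_equal(s$ci_hi, 0.4)
})

test_that("bootstrap intervals contain the mean and match an oracle", {
  set.seed(2)
  v <- as.numeric(runif(50) < 0.5)
  ncd <- tibble::tibble(cell_id = sprintf("c%d", 1:50), ncd_1 = v)
  cl <- tibble::tibble(cell_id = ncd$cell_id, cluster = "all")
  s <- summarize_ncd(ncd, cl, n_boot = 10000, seed = 3)
  expect_gte(s$mean_ncd, s$ci_lo)
  expect_lte(s$mean_ncd, s$ci_hi)
  oracle <- boot_ci_oracle(v, n_boot = 10000, seed = 3)
  half <- (s$ci_hi - s$ci_lo) / 2
  half_oracle <- diff(oracle) / 2
  expect_lt(abs(half - half_oracle) / half_oracle, 0.2)
})

test_that("summaries demand complete labels and non-empty clusters", {
  ncd <- tibble::tibble(cell_id = c("a", "b"), ncd_1 = c(1, 2))
  expect_error(summarize_ncd(ncd, tibble::tibble(cell_id = "a",
                                                 cluster = "X"),
                             n_boot = 100),
               "unlabeled")
  expect_error(summarize_ncd(ncd,
                             tibble::tibble(cell_id = c("a", "b"),
                                            cluster = "X"),
                             n_boot = 10),
               "n_boot")
})

test_that("the plotting outlier filter screens on |z| without touching data", {
  set.seed(5)
  d <- tibble::tibble(x = c(rnorm(30), 50), y = c(rnorm(30), -40))
  keep <- plot_inlier_filter(d, c("x", "y"))
  expect_false(keep[31])
  expect_true(mean(keep[1:30]) > 0.9)
})
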