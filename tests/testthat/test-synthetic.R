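test_that("planted spike times follow delay + geometric ISI accommodation", {
  nrn <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 50, isi_base_ms = 20,
                          accommodation_rate = 1, noise_sd = 0)
  stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                         amplitude_na = 0.3)  # 1.5x rheobase reference
  sp <- detect_spikes(stimulate(nrn, stim))
  expect_equal(head(sp$spike_ms, 3), c(1050, 1070, 1090), tolerance = 1e-9)

  acc <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 50, isi_base_ms = 20,
                          accommodation_rate = 1.2, noise_sd = 0)
  spa <- detect_spikes(stimulate(acc, stim))
  isi <- diff(spa$spike_ms)
  expect_equal(isi[2] / isi[1], 1.2, tolerance = 0.02)
})

test_that("intrinsically spiking models fire without stimulation", {
  nrn <- synthetic_neuron(intrinsic_spiking = TRUE, noise_sd = 0)
  stim <- build_protocol("square", onset_ms = 0, duration_ms = 1000,
                         amplitude_na = 0)
  sp <- detect_spikes(stimulate(nrn, stim))
  expect_gte(nrow(sp), 1)
})

test_that("identical spec and seed give identical traces", {
  nrn <- synthetic_neuron(noise_sd = 0.5, seed = 9)
  stim <- build_protocol("square", amplitude_na = 0.3)
  t1 <- stimulate(nrn, stim)
  t2 <- stimulate(nrn, stim)
  expect_identical(t1$voltage_mv, t2$voltage_mv)
})

test_that("noise-free step tables are exactly linear", {
  series <- complexity_current_series(1, 0.9)
  ap <- c(0, 0, 2 * (1:11))
  tbl <- generate_step_count_table(1000, 200, series, ap, "none")
  expect_equal(tbl$steps, 1000 + 200 * ap)
  expect_equal(unname(residuals(lm(steps ~ ap_count, tbl))), rep(0, 13),
               tolerance = 1e-9)

  flat <- generate_step_count_table(1500, 0, series, ap, "none")
  expect_true(all(flat$steps == 1500))
})

test_that("poisson step tables are seeded and length-checked", {
  series <- complexity_current_series(1, 0.9)
  ap <- c(0, 0, 2 * (1:11))
  t1 <- generate_step_count_table(1000, 200, series, ap, "poisson", seed = 5)
  t2 <- generate_step_count_table(1000, 200, series, ap, "poisson", seed = 5)
  expect_identical(t1, t2)
  expect_error(generate_step_count_table(1000, 200, series, ap[-1]),
               "length mismatch")
})

test_that("a channel held far below its activation threshold stays closed", {
  spec <- channel_family_spec("Kv", activation_v_half = -20)
  pr <- list(activation = clamp_protocol("activation",
                                         step_mv = c(-90, -80),
                                         hold_mv = -100),
             deactivation = clamp_protocol("deactivation", hold_mv = -100,
                                           step_mv = c(-100, -90)),
             inactivation = clamp_protocol("inactivation", hold_mv = -100,
                                           step_mv = c(-100, -90)))
  pr$deactivation$activating_mv <- -90  # never activate
  pr$inactivation$test_mv <- -90
  resp <- generate_channel_response_set(list(ch = spec), pr)
  expect_lt(max(resp$conductance), 1e-4)
})

test_that("identical channel specs give identical response tables", {
  specs <- list(a = channel_family_spec("Nav"), b = channel_family_spec("Nav"))
  resp <- generate_channel_response_set(specs)
  a <- resp[resp$model_id == "a", setdiff(names(resp), "model_id")]
  b <- resp[resp$model_id == "b", setdiff(names(resp), "model_id")]
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("condensed responses separate families: within < between distance", {
  set.seed(21)
  mk <- function(family, n) {
    base <- channel_family_spec(family)
    lapply(seq_len(n), function(i) {
      channel_family_spec(family,
        activation_v_half = base$activation_v_half + rnorm(1, sd = 2),
        activation_tau_ms = base$activation_tau_ms * exp(rnorm(1, sd = 0.1)))
    })
  }
  specs <- c(mk("Kv", 10), mk("Nav", 10))
  names(specs) <- sprintf("m%02d", 1:20)
  resp <- generate_channel_response_set(specs)
  cm <- condense_responses(resp, "activation", grid_points = 64)
  d <- as.matrix(dist(cm))
  fam <- rep(c("Kv", "Nav"), each = 10)
  within <- mean(d[outer(fam, fam, "==") & upper.tri(d)])
  between <- mean(d[outer(fam, fam, "!=") & upper.tri(d)])
  expect_lt(within, between)
})

test_that("channel response generation requires all three protocol kinds", {
  pr <- standard_clamp_protocols()
  expect_error(
    generate_channel_response_set(list(a = channel_family_spec("Kv")),
                                  pr[c("activation", "deactivation")]),
    "missing protocol kind")
})

test_that("conductance files round-trip through the parser", {
  gen <- generate_cell_conductance_files(4, c("kv_a", "nav_b"), seed = 3)
  tbl <- read_conductance_table(gen$paths, c("kv_a", "nav_b"))
  expect_equal(as.data.frame(tbl), as.data.frame(gen$truth),
               tolerance = 1e-5)
  unlink(dirname(gen$paths[1]), recursive = TRUE)
})

test_that("conductance files are byte-identical under a fixed seed", {
  g1 <- generate_cell_conductance_files(2, "kv_a", seed = 4)
  g2 <- generate_cell_conductance_files(2, "kv_a", seed = 4)
  expect_identical(readLines(g1$paths[1]), readLines(g2$paths[1]))
  unlink(dirname(c(g1$paths[1], g2$paths[1])), recursive = TRUE)
  expect_error(
    generate_cell_conductance_files(2, "kv_a",
                                    density_law = list(meanlog = 0,
                                                       sdlog = -1)),
    "negative density")
})

test_that("planted feature matrices honor k, seed and separation", {
  one <- generate_planted_feature_matrix(1, 20, seed = 2)
  expect_true(all(one$labels == 1))
  m1 <- generate_planted_feature_matrix(3, 10, separation = 10, seed = 6)
  m2 <- generate_planted_feature_matrix(3, 10, separation = 10, seed = 6)
  expect_identical(m1$matrix, m2$matrix)
  km <- withr::with_seed(1,
    kmeans(as.matrix(m1$matrix[, -1]), centers = 3, nstart = 10))
  expect_equal(ari(km$cluster, m1$labels), 1.0)
})
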