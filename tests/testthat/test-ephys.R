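test_that("spike detection finds inserted APs and ignores flat traces", {
  flat <- tibble::tibble(time_ms = seq(0, 100, by = 0.1),
                         voltage_mv = -70)
  expect_equal(nrow(detect_spikes(flat)), 0)
  expect_error(detect_spikes(flat[0, ]), "empty trace")

  nrn <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 100, isi_base_ms = 300,
                          accommodation_rate = 1, noise_sd = 0)
  stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                         amplitude_na = 0.3)
  sp <- detect_spikes(stimulate(nrn, stim))
  expect_equal(sp$spike_ms, c(1100, 1400, 1700), tolerance = 0.11)
})

test_that("derivative fallback detects spikes in traces resting at 0 mV", {
  abstract <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 50,
                               isi_base_ms = 100, accommodation_rate = 1,
                               resting_mv = 0, ap_amplitude_mv = 30,
                               noise_sd = 0)
  stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                         amplitude_na = 0.3)
  sp <- detect_spikes(stimulate(abstract, stim))
  expect_gte(nrow(sp), 3)
  expect_equal(sp$spike_ms[1], 1050, tolerance = 0.11)
})

test_that("rheobase bisection recovers the planted threshold within 1%", {
  nrn <- synthetic_neuron(rheobase_na = 0.5, noise_sd = 0)
  rb <- find_rheobase(nrn)
  expect_false(rb$non_positive)
  expect_lt(abs(rb$rheobase_na - 0.5) / 0.5, 0.01)
  expect_lt(rb$sub_rheobase_na, rb$rheobase_na)
})

test_that("rheobase search flags intrinsic spikers and errors on non-spikers", {
  intrinsic <- synthetic_neuron(intrinsic_spiking = TRUE, noise_sd = 0)
  expect_true(find_rheobase(intrinsic)$non_positive)

  dead <- function(stimulus, ...) {
    tr <- tibble::tibble(time_ms = stimulus$time_ms, voltage_mv = -70)
    attr(tr, "stimulus") <- stimulus
    class(tr) <- c("voltage_trace", class(tr))
    tr
  }
  expect_error(find_rheobase(dead), "no rheobase")
})

test_that("feature extraction recovers planted spike-train parameters", {
  nrn <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 50, isi_base_ms = 40,
                          accommodation_rate = 1, ap_amplitude_mv = 100,
                          ap_width_ms = 1, noise_sd = 0)
  f <- compute_features(nrn, "m1")
  dt <- 0.1
  expect_equal(f$delay_first_ap_ms_15x, 50, tolerance = dt * 1.01)
  expect_equal(f$isi_median_ms_15x, 40, tolerance = 1e-9)
  expect_equal(f$ap1_amplitude_mv_15x, 100, tolerance = 1)
  expect_equal(f$ap1_halfwidth_ms_15x, 1, tolerance = 0.15)
  expect_equal(f$accommodation_ss_pct_15x, 0, tolerance = 1e-9)
  # ramp at 1 rheobase/s crosses threshold 1000 ms after onset
  expect_equal(f$time_to_first_ramp_spike_ms, 1000, tolerance = 1)
  # 3x stimulus compresses delay and intervals by 2 (documented rule)
  expect_equal(f$delay_first_ap_ms_30x, 25, tolerance = dt * 1.01)
  expect_equal(f$isi_median_ms_30x, 20, tolerance = 1e-9)
})

test_that("median ISI comes from the inter-spike intervals of the train", {
  # spikes at 100, 120, 150, 190 ms after onset -> ISIs {20, 30, 40}
  dt <- 0.1
  t <- seq(0, 2500 - dt, by = dt)
  v <- rep(-70, length(t))
  for (ts in 1000 + c(100, 120, 150, 190)) {
    v[round(ts / dt) + 1] <- 30
  }
  tr <- tibble::tibble(time_ms = t, voltage_mv = v)
  stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                         amplitude_na = 0.3, sampling_interval_ms = dt)
  attr(tr, "stimulus") <- stim
  class(tr) <- c("voltage_trace", class(tr))
  props <- neurochar:::train_properties(tr, detect_spikes(tr))
  expect_equal(props$isi_median_ms, 30, tolerance = 1e-9)
  expect_equal(props$spike_count, 4)
})

test_that("every model receives exactly 42 named properties", {
  expect_length(feature_names(), 42)
  expect_length(druckmann_feature_names(), 38)
  f <- compute_features(synthetic_neuron(noise_sd = 0), "a")
  expect_true(all(feature_names() %in% names(f)))
  fi <- compute_features(synthetic_neuron(intrinsic_spiking = TRUE,
                                          noise_sd = 0), "b")
  expect_true(all(feature_names() %in% names(fi)))
  expect_true(fi$non_positive_rheobase)
  expect_true(is.na(fi$delay_first_ap_ms_15x))  # flagged missing, not zero
  expect_gte(fi$resting_ap_count, 1)
})

test_that("accommodation is zero for constant trains, monotone in the rate", {
  mk <- function(rate) compute_features(
    synthetic_neuron(rheobase_na = 0.2, delay_ms = 50, isi_base_ms = 30,
                     accommodation_rate = rate, noise_sd = 0), "m")
  f1 <- mk(1.0); f2 <- mk(1.05); f3 <- mk(1.1)
  expect_equal(f1$accommodation_ss_pct_15x, 0, tolerance = 1e-9)
  expect_gt(f2$accommodation_ss_pct_15x, 0)
  expect_gt(f3$accommodation_ss_pct_15x, f2$accommodation_ss_pct_15x)
})

test_that("bi-sigmoid fits recover planted inflection frequencies", {
  f <- seq(29, 143, length.out = 12)
  for (band in list(c(50, 110), c(60, 120))) {
    y <- 1 + 2 * plogis((f - band[1]) / 6) * plogis((band[2] - f) / 6)
    fit <- fit_freq_filter(f, y)
    expect_true(fit$converged)
    expect_lt(abs(fit$freq_pass_above_hz - band[1]) / band[1], 0.1)
    expect_lt(abs(fit$freq_pass_below_hz - band[2]) / band[2], 0.1)
  }
  flat <- fit_freq_filter(f, rep(3, 12))
  expect_false(flat$converged)
  expect_true(is.na(flat$freq_pass_above_hz))
})

test_that("missing values are filled by declared policy only", {
  m <- tibble::tibble(a = c(1, NA, 3), b = c(2, 4, 6))
  pol <- tibble::tibble(feature = c("a", "b"), policy = c("mean", "mean"))
  expect_equal(fill_missing(m, pol)$a, c(1, 2, 3))
  expect_identical(fill_missing(tibble::tibble(a = 1:3 * 1.0), pol),
                   tibble::tibble(a = 1:3 * 1.0))
  expect_equal(fill_missing(tibble::tibble(a = c(5, NA)),
                            tibble::tibble(feature = "a", policy = "min"))$a,
               c(5, 5))
  expect_error(fill_missing(tibble::tibble(z = c(1, NA)), pol), "no declared")
  expect_error(fill_missing(tibble::tibble(a = c(NA_real_, NA_real_)), pol),
               "undefined mean")
})

test_that("bi-symmetric log is odd, fixed at 0, and matches the closed form", {
  expect_identical(bilog_transform(0), 0)
  x <- c(0.1, 1, 7, 1000, 1e6)
  expect_equal(bilog_transform(-x), -bilog_transform(x), tolerance = 1e-14)
  # frozen value from a 30-digit evaluation of log10(1 + 1000 * ln 10)
  expect_equal(bilog_transform(1000), 3.36240425945181947,
               tolerance = 1e-14)
  expect_true(all(diff(bilog_transform(seq(-5, 5, by = 0.01))) > 0))
})

test_that("standardization uses population SD and guards constant columns", {
  z <- standardize(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(z$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_warning(zc <- standardize(tibble::tibble(a = rep(4, 5))),
                 "zero-variance")
  expect_true(all(zc$a == 0))
  set.seed(1)
  big <- standardize(tibble::tibble(x = rnorm(50, 100, 3), y = runif(50)))
  expect_lt(max(abs(colMeans(as.matrix(big)))), 1e-12)
})

test_that("preparation applies fill, bilog and z-score in that order", {
  m <- tibble::tibble(a = c(-1000, 1, NA, 50), b = c(1, 2, 3, 4))
  pol <- tibble::tibble(feature = c("a", "b"), policy = "mean")
  prepared <- prepare_feature_matrix(m, pol, id_cols = character(0))
  by_hand <- standardize(
    dplyr::mutate(fill_missing(m, pol),
                  dplyr::across(dplyr::everything(), bilog_transform)))
  expect_equal(as.data.frame(prepared), as.data.frame(by_hand),
               tolerance = 1e-12)
  # wrong order (transform before fill) yields a different matrix
  wrong <- standardize(
    fill_missing(dplyr::mutate(m, dplyr::across(dplyr::everything(),
                                                bilog_transform)), pol))
  expect_gt(max(abs(as.matrix(prepared) - as.matrix(wrong))), 0.01)
})
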