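#' Canonical names of the 42 electrophysiology properties
#'
#' The characterization comprises 38 Druckmann-style action-potential and
#' spike-train properties — 19 measures evaluated at the 1.5x ("normal") and
#' 3.0x ("strong") rheobase square stimuli — plus four additional properties:
#' the resting action-potential count, the time to the first spike under a
#' 1 rheobase/s ramp, and the pass-above / pass-below inflection frequencies
#' of a bi-sigmoidal ("hat") fit to triple-pulse responses.
#'
#' @return Character vector of length 42 (or 38 for the Druckmann-style
#'   subset).
#' @export
feature_names <- function() {
  c(druckmann_feature_names(),
    "resting_ap_count", "time_to_first_ramp_spike_ms",
    "freq_pass_above_hz", "freq_pass_below_hz")
}

#' @rdname feature_names
#' @export
druckmann_feature_names <- function() {
  base <- c("spike_count", "delay_first_ap_ms", "delay_second_ap_ms",
            "mean_firing_rate_hz", "isi_mean_ms", "isi_median_ms", "isi_cv",
            "isi_first_ms", "isi_last_ms", "accommodation_ss_pct",
            "accommodation_rate_pct", "ap1_amplitude_mv", "ap2_amplitude_mv",
            "ap_amplitude_mean_mv", "ap_amplitude_adaptation_pct",
            "ap1_halfwidth_ms", "ap_halfwidth_mean_ms", "ahp_depth_mean_mv",
            "adaptation_index")
  c(paste0(base, "_15x"), paste0(base, "_30x"))
}

# the 19 per-stimulus-strength spike/train properties; NA encodes "could not
# be computed" (e.g. 2nd AP amplitude when the model spiked once)
train_properties <- function(trace, spikes) {
  onset <- attr(spikes, "stimulus_onset")
  offset <- attr(spikes, "stimulus_offset")
  baseline <- stats::median(trace$voltage_mv[trace$time_ms < onset])
  st <- spikes$spike_ms[spikes$spike_ms >= onset & spikes$spike_ms < offset]
  n <- length(st)
  dur_s <- (offset - onset) / 1000
  isi <- if (n >= 2) diff(st) else numeric(0)

  shapes <- measure_spike_shapes(trace, tibble(spike_ms = st), baseline)

  # steady-state accommodation: percent change of the mean late-train ISI
  # (intervals ending in the last 25% of the stimulus window) vs the first ISI
  acc_ss <- NA_real_
  if (length(isi) >= 2) {
    late <- isi[st[-1] >= offset - 0.25 * (offset - onset)]
    if (length(late) >= 1) acc_ss <- 100 * (mean(late) - isi[1]) / isi[1]
  }
  acc_rate <- if (length(isi) >= 2) {
    100 * mean(diff(isi) / head(isi, -1))
  } else NA_real_

  half <- onset + (offset - onset) / 2
  n_early <- sum(st < half)
  n_late <- n - n_early
  adapt_idx <- if (n > 0) (n_late - n_early) / n else NA_real_

  tibble(
    spike_count = n,
    delay_first_ap_ms = if (n >= 1) st[1] - onset else NA_real_,
    delay_second_ap_ms = if (n >= 2) st[2] - onset else NA_real_,
    mean_firing_rate_hz = n / dur_s,
    isi_mean_ms = if (n >= 2) mean(isi) else NA_real_,
    isi_median_ms = if (n >= 2) stats::median(isi) else NA_real_,
    isi_cv = if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_,
    isi_first_ms = if (n >= 2) isi[1] else NA_real_,
    isi_last_ms = if (n >= 2) isi[length(isi)] else NA_real_,
    accommodation_ss_pct = acc_ss,
    accommodation_rate_pct = acc_rate,
    ap1_amplitude_mv = if (n >= 1) shapes$amplitude_mv[1] else NA_real_,
    ap2_amplitude_mv = if (n >= 2) shapes$amplitude_mv[2] else NA_real_,
    ap_amplitude_mean_mv = if (n >= 1) mean(shapes$amplitude_mv) else NA_real_,
    ap_amplitude_adaptation_pct = if (n >= 2) {
      100 * (shapes$amplitude_mv[n] - shapes$amplitude_mv[1]) /
        shapes$amplitude_mv[1]
    } else NA_real_,
    ap1_halfwidth_ms = if (n >= 1) shapes$halfwidth_ms[1] else NA_real_,
    ap_halfwidth_mean_ms = if (n >= 1) mean(shapes$halfwidth_ms) else NA_real_,
    # exclude the last spike: its AHP window is truncated by stimulus offset
    ahp_depth_mean_mv = if (n >= 2) mean(shapes$ahp_mv[-n]) else NA_real_,
    adaptation_index = adapt_idx
  )
}

#' Fit a bi-sigmoidal ("hat") frequency-response curve
#'
#' Models the number of spikes elicited by pulse triples as a product of two
#' opposing logistic sigmoids of pulse frequency,
#' `count = b + A * sigm((f - f_lo)/s) * sigm((f_hi - f)/s)`, and returns the
#' two inflection frequencies: `f_lo` is the pass-above and `f_hi` the
#' pass-below frequency-filter parameter.
#'
#' @param freq_hz Pulse frequencies (Hz).
#' @param counts Spike counts at each frequency.
#' @return One-row tibble `freq_pass_above_hz`, `freq_pass_below_hz`,
#'   `converged`. Returns `NA`s (with `converged = FALSE`) when the profile
#'   carries no band structure (constant counts) or the fit fails.
#' @export
fit_freq_filter <- function(freq_hz, counts) {
  stop_if_not(length(freq_hz) == length(counts) && length(freq_hz) >= 4,
              "need >= 4 (frequency, count) pairs")
  na_fit <- tibble(freq_pass_above_hz = NA_real_,
                   freq_pass_below_hz = NA_real_, converged = FALSE)
  if (stats::sd(counts) == 0) return(na_fit)
  rng <- range(freq_hz)
  span <- diff(rng)
  hat <- function(p) {
    p["b"] + p["A"] * plogis((freq_hz - p["f_lo"]) / p["s"]) *
      plogis((p["f_hi"] - freq_hz) / p["s"])
  }
  resid_fn <- function(p) counts - hat(p)
  start <- c(b = min(counts), A = diff(range(counts)),
             f_lo = rng[1] + 0.25 * span, f_hi = rng[2] - 0.25 * span,
             s = span / 10)
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(b = -Inf, A = 0, f_lo = rng[1] - span, f_hi = rng[1] - span,
              s = 1e-3),
    upper = c(b = Inf, A = Inf, f_lo = rng[2] + span, f_hi = rng[2] + span,
              s = span),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info == 0) return(na_fit)
  cf <- fit$par
  # an identified band must lie inside the probed range in the right order
  if (cf["f_lo"] >= cf["f_hi"]) return(na_fit)
  tibble(freq_pass_above_hz = unname(cf["f_lo"]),
         freq_pass_below_hz = unname(cf["f_hi"]), converged = TRUE)
}

#' Compute the 42-property electrophysiology characterization of one model
#'
#' Runs the full current-clamp battery against a stimulable model: rheobase
#' search, square injections at 1.5x and 3.0x rheobase (19 Druckmann-style
#' properties each), a 1 rheobase/s ramp (time to first ramp spike), a
#' no-stimulus window (resting action-potential count) and short-square
#' triples over `triple_freqs_hz` fitted with [fit_freq_filter()].
#' Properties that cannot be computed (no spikes, non-positive rheobase, no
#' band structure) are returned as `NA` — they are flagged missing, never
#' silently zero — and later resolved by [fill_missing()].
#'
#' @param model A stimulable model (see [stimulate()]).
#' @param model_id Identifier stored in the output row.
#' @param triple_freqs_hz Pulse-triple frequencies (Hz).
#' @param sampling_interval_ms Trace sampling interval (ms).
#' @param max_current_na Upper bound for the rheobase search.
#' @return A one-row tibble: `model_id`, `rheobase_na`, `non_positive_rheobase`
#'   and the 42 properties of [feature_names()].
#' @export
compute_features <- function(model, model_id = "model",
                             triple_freqs_hz = seq(29, 143, length.out = 9),
                             sampling_interval_ms = 0.1,
                             max_current_na = 10) {
  dt <- sampling_interval_ms

  # resting behaviour: 1 s with no stimulation
  rest_stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                              amplitude_na = 0, sampling_interval_ms = dt)
  rest_spikes <- detect_spikes(stimulate(model, rest_stim))
  resting_ap_count <- sum(rest_spikes$spike_ms >= 1000 &
                            rest_spikes$spike_ms < 2000)

  rb <- tryCatch(find_rheobase(model, max_current_na = max_current_na,
                               sampling_interval_ms = dt),
                 error = function(e) tibble(rheobase_na = NA_real_,
                                            sub_rheobase_na = NA_real_,
                                            non_positive = FALSE,
                                            n_probes = NA_integer_))
  empty <- setNames(rep(list(NA_real_), length(druckmann_feature_names())),
                    druckmann_feature_names())
  out <- c(list(model_id = model_id,
                rheobase_na = rb$rheobase_na,
                non_positive_rheobase = rb$non_positive),
           empty,
           list(resting_ap_count = as.numeric(resting_ap_count),
                time_to_first_ramp_spike_ms = NA_real_,
                freq_pass_above_hz = NA_real_,
                freq_pass_below_hz = NA_real_))

  if (!isTRUE(rb$non_positive) && !is.na(rb$rheobase_na)) {
    rheo <- rb$rheobase_na
    for (mult in c(1.5, 3.0)) {
      stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                             amplitude_na = mult * rheo,
                             sampling_interval_ms = dt)
      trace <- stimulate(model, stim)
      props <- train_properties(trace, detect_spikes(trace))
      suffix <- if (mult == 1.5) "_15x" else "_30x"
      out[paste0(names(props), suffix)] <- as.list(props)
    }

    ramp <- build_protocol("ramp", onset_ms = 1000, duration_ms = 2000,
                           slope_rb_per_s = 1, rheobase_na = rheo,
                           sampling_interval_ms = dt)
    rtrace <- stimulate(model, ramp)
    rs <- detect_spikes(rtrace)
    first_ramp <- rs$spike_ms[rs$spike_ms >= 1000]
    if (length(first_ramp) > 0) {
      out$time_to_first_ramp_spike_ms <- first_ramp[1] - 1000
    }

    counts <- vapply(triple_freqs_hz, function(f) {
      stim <- build_protocol("short_square_triple", onset_ms = 200,
                             duration_ms = 2, amplitude_na = 2 * rheo,
                             pulse_frequency_hz = f,
                             sampling_interval_ms = dt, tail_ms = 100)
      nrow(detect_spikes(stimulate(model, stim)))
    }, numeric(1))
    ff <- fit_freq_filter(triple_freqs_hz, counts)
    if (isTRUE(ff$converged)) {
      out$freq_pass_above_hz <- ff$freq_pass_above_hz
      out$freq_pass_below_hz <- ff$freq_pass_below_hz
    }
  }
  as_tibble(out[c("model_id", "rheobase_na", "non_positive_rheobase",
                  feature_names())])
}

#' Feature matrix for a collection of models
#'
#' @param models Named list of stimulable models.
#' @param ... Passed to [compute_features()].
#' @return Tibble with one row per model (42 properties plus identifiers).
#' @export
compute_feature_matrix <- function(models, ...) {
  ids <- names(models) %||% paste0("model_", seq_along(models))
  purrr::map2_dfr(models, ids, function(m, id) compute_features(m, id, ...))
}
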