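#' Detect action potentials in a voltage trace
#'
#' Events are detected as upward crossings of a fixed voltage threshold
#' (default 0 mV) with refractory merging. Traces whose resting (median)
#' potential already sits at or above the voltage threshold — e.g. abstract
#' integrate-and-fire style models resting at 0 mV — fall back to a
#' derivative detector: upward crossings of `dvdt_threshold` mV/ms.
#'
#' @param trace A uniformly sampled `voltage_trace` tibble (`time_ms`,
#'   `voltage_mv`).
#' @param threshold_mv Voltage threshold (mV).
#' @param dvdt_threshold Derivative threshold (mV/ms) for the fallback.
#' @param refractory_ms Minimum separation between detected spikes (ms).
#' @return A `spike_train` tibble with column `spike_ms`; attributes
#'   `stimulus_onset` / `stimulus_offset` when the trace carries its stimulus.
#' @export
detect_spikes <- function(trace, threshold_mv = 0, dvdt_threshold = 20,
                          refractory_ms = 2) {
  stop_if_not(is.data.frame(trace) && nrow(trace) > 0, "empty trace")
  t <- trace$time_ms
  v <- trace$voltage_mv
  dt <- t[2] - t[1]

  if (stats::median(v) >= threshold_mv) {
    dv <- c(0, diff(v)) / dt
    up <- which(dv >= dvdt_threshold & c(0, head(dv, -1)) < dvdt_threshold)
  } else {
    up <- which(v >= threshold_mv & c(-Inf, head(v, -1)) < threshold_mv)
  }
  times <- t[up]
  if (length(times) > 1) {
    # refractory merging: drop crossings within the refractory window of the
    # previously kept spike
    out <- numeric(0)
    last <- -Inf
    for (x in times) {
      if (x - last >= refractory_ms) {
        out <- c(out, x)
        last <- x
      }
    }
    times <- out
  }
  st <- tibble(spike_ms = times)
  stim <- attr(trace, "stimulus", exact = TRUE)
  if (!is.null(stim)) {
    info <- stim_info(stim)
    attr(st, "stimulus_onset") <- info$onset_ms
    attr(st, "stimulus_offset") <- info$onset_ms + info$duration_ms
  }
  class(st) <- c("spike_train", class(st))
  st
}

#' Find a model's rheobase by bracketed bisection
#'
#' Searches for the smallest square-current amplitude whose 1 s injection
#' (after a 1 s delay) elicits at least one spike. If the model spikes with
#' no stimulation it is flagged as having a non-positive rheobase
#' (intrinsically spiking); if it never spikes up to `max_current_na` an
#' error is raised. The lower bisection bracket at termination is recorded as
#' the largest known sub-rheobase current.
#'
#' @param model A stimulable model (see [stimulate()]).
#' @param max_current_na Largest amplitude probed (nA).
#' @param rel_tol Relative bracket tolerance at termination.
#' @param max_iter Maximum bisection iterations.
#' @param sampling_interval_ms Trace sampling interval used for the probes.
#' @return A one-row tibble: `rheobase_na`, `sub_rheobase_na`,
#'   `non_positive` (logical), `n_probes`. For intrinsically spiking models
#'   `rheobase_na` is `NA` and `non_positive` is `TRUE`.
#' @export
find_rheobase <- function(model, max_current_na = 10, rel_tol = 0.01,
                          max_iter = 30, sampling_interval_ms = 0.1) {
  probe <- function(amp) {
    stim <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
                           amplitude_na = amp,
                           sampling_interval_ms = sampling_interval_ms)
    nrow(detect_spikes(stimulate(model, stim))) > 0
  }
  n_probes <- 1L
  if (probe(0)) {
    return(tibble(rheobase_na = NA_real_, sub_rheobase_na = NA_real_,
                  non_positive = TRUE, n_probes = n_probes))
  }
  # geometric scan upward for the first spiking amplitude
  grid <- 0.05 * 2^(0:ceiling(log2(max_current_na / 0.05)))
  grid <- c(grid[grid < max_current_na], max_current_na)
  lo <- 0
  hi <- NA_real_
  for (a in grid) {
    n_probes <- n_probes + 1L
    if (probe(a)) { hi <- a; break }
    lo <- a
  }
  stop_if_not(!is.na(hi), paste0("no rheobase <= max current (",
                                 max_current_na, " nA)"))
  iter <- 0L
  while ((hi - lo) / hi > rel_tol && iter < max_iter) {
    mid <- (hi + lo) / 2
    n_probes <- n_probes + 1L
    if (probe(mid)) hi <- mid else lo <- mid
    iter <- iter + 1L
  }
  tibble(rheobase_na = hi, sub_rheobase_na = lo,
         non_positive = FALSE, n_probes = n_probes)
}

# per-spike shape measurements relative to the pre-stimulus baseline:
# amplitude (peak - baseline), half-width (time spent above half-amplitude),
# AHP depth (baseline - minimum before the next spike)
measure_spike_shapes <- function(trace, spikes, baseline_mv) {
  t <- trace$time_ms
  v <- trace$voltage_mv
  dt <- t[2] - t[1]
  n <- length(t)
  times <- spikes$spike_ms
  k <- length(times)
  if (k == 0) {
    return(tibble(amplitude_mv = numeric(0), halfwidth_ms = numeric(0),
                  ahp_mv = numeric(0)))
  }
  bounds <- c(times[-1], t[n])
  purrr::map_dfr(seq_len(k), function(j) {
    i0 <- max(1L, round(times[j] / dt) + 1L)
    i1 <- min(n, round(bounds[j] / dt))
    seg <- v[i0:i1]
    peak <- max(seg)
    amp <- peak - baseline_mv
    half <- baseline_mv + amp / 2
    above <- seg >= half
    # contiguous run containing the peak
    pk <- which.max(seg)
    lo <- pk
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- pk
    while (hi < length(seg) && above[hi + 1]) hi <- hi + 1
    tibble(amplitude_mv = amp,
           halfwidth_ms = (hi - lo + 1) * dt,
           ahp_mv = baseline_mv - min(seg))
  })
}
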