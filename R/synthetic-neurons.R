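#' Synthetic spiking neuron model with known ground truth
#'
#' A phenomenological spiking model: stylized action-potential waveforms are
#' inserted at analytically computed spike times, so every downstream feature
#' (delay, inter-spike intervals, accommodation, spike shape) has an exact
#' known value. The model is *not* conductance-based; it exists so that the
#' characterization pipeline can be validated against planted parameters.
#'
#' Spike-time rules (square stimulus of amplitude `I >= rheobase_na`, the
#' reference strength being 1.5x rheobase):
#' * first spike at `onset + delay_ms * (1.5 * rheobase / I)` — the delay
#'   shrinks monotonically with stimulus strength;
#' * subsequent inter-spike intervals
#'   `isi_base_ms * (1.5 * rheobase / I) * accommodation_rate^k`,
#'   `k = 0, 1, ...` — a rate above 1 yields progressively longer intervals
#'   (spike-frequency accommodation);
#' * ramp stimuli spike when the instantaneous current reaches rheobase, with
#'   intervals scaled by the instantaneous current;
#' * each pulse of a `short_square`/`short_square_triple` stimulus with
#'   amplitude `>= rheobase` triggers one spike at a 1 ms latency; for the
#'   2nd/3rd pulse of a triple with a configured `freq_band`, the spike occurs
#'   only when the pulse frequency lies inside the band (a band-pass
#'   frequency-filtering cell);
#' * `intrinsic_spiking` models fire from `delay_ms` onward at `isi_base_ms`
#'   regardless of the stimulus (non-positive rheobase phenotype).
#'
#' @param rheobase_na Threshold current (nA) for sustained square stimuli.
#' @param delay_ms Delay to the first spike at the 1.5x-rheobase reference
#'   stimulus (ms).
#' @param isi_base_ms First inter-spike interval at the reference stimulus
#'   (ms), `> 0`.
#' @param accommodation_rate Multiplicative per-interval ISI drift (1 =
#'   constant intervals; > 1 = accommodating).
#' @param ap_amplitude_mv Spike amplitude above resting potential (mV).
#' @param ap_width_ms Spike half-width (ms), `> 0`.
#' @param ahp_depth_mv After-hyperpolarization depth below resting (mV).
#' @param resting_mv Resting potential (mV). Abstract integrate-and-fire
#'   style models may rest at 0 mV.
#' @param intrinsic_spiking Logical; fires without stimulation if `TRUE`.
#' @param freq_band Optional `c(lo_hz, hi_hz)` band within which pulse
#'   triples elicit all three spikes (outside the band only the first pulse
#'   spikes); `NULL` means no frequency filtering.
#' @param noise_sd Gaussian noise added to the trace (mV).
#' @param seed Integer seed; identical spec and stimulus give an identical
#'   trace.
#' @return A `synthetic_neuron` object usable with [stimulate()] and all
#'   characterization functions.
#' @examples
#' nrn <- synthetic_neuron(rheobase_na = 0.2, delay_ms = 50, noise_sd = 0)
#' stim <- build_protocol("square", amplitude_na = 0.3)
#' trace <- stimulate(nrn, stim)
#' detect_spikes(trace)
#' @export
synthetic_neuron <- function(rheobase_na = 0.2,
                             delay_ms = 50,
                             isi_base_ms = 40,
                             accommodation_rate = 1.05,
                             ap_amplitude_mv = 100,
                             ap_width_ms = 1,
                             ahp_depth_mv = 10,
                             resting_mv = -70,
                             intrinsic_spiking = FALSE,
                             freq_band = NULL,
                             noise_sd = 0.25,
                             seed = 1L) {
  stop_if_not(is_number(isi_base_ms) && isi_base_ms > 0, "isi_base_ms must be > 0")
  stop_if_not(is_number(ap_width_ms) && ap_width_ms > 0, "ap_width_ms must be > 0")
  stop_if_not(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  if (!is.null(freq_band)) {
    stop_if_not(is.numeric(freq_band) && length(freq_band) == 2L &&
                  freq_band[1] < freq_band[2], "freq_band must be c(lo, hi)")
  }
  structure(
    list(rheobase_na = rheobase_na, delay_ms = delay_ms,
         isi_base_ms = isi_base_ms, accommodation_rate = accommodation_rate,
         ap_amplitude_mv = ap_amplitude_mv, ap_width_ms = ap_width_ms,
         ahp_depth_mv = ahp_depth_mv, resting_mv = resting_mv,
         intrinsic_spiking = isTRUE(intrinsic_spiking),
         freq_band = freq_band, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_neuron"
  )
}

#' Apply a stimulus to a model and obtain its voltage response
#'
#' Generic entry point used by the feature-extraction stage: any object that
#' can answer "what is your membrane potential under this stimulus?" can be
#' characterized. Methods exist for [synthetic_neuron()] specs and for plain
#' functions `function(stimulus) -> trace`.
#'
#' @param model A stimulable model.
#' @param stimulus A `stimulus_waveform` from [build_protocol()].
#' @param ... Passed to methods.
#' @return A `voltage_trace` tibble (`time_ms`, `voltage_mv`) carrying the
#'   stimulus as attribute `"stimulus"`.
#' @export
stimulate <- function(model, stimulus, ...) UseMethod("stimulate")

#' @export
stimulate.function <- function(model, stimulus, ...) model(stimulus, ...)

#' @rdname stimulate
#' @export
stimulate.synthetic_neuron <- function(model, stimulus, ...) {
  generate_voltage_response(model, stimulus)
}

#' Generate the voltage response of a synthetic neuron
#'
#' @param spec A [synthetic_neuron()] specification.
#' @param stimulus A sampled `stimulus_waveform`.
#' @return A `voltage_trace` tibble with columns `time_ms`, `voltage_mv`.
#' @export
generate_voltage_response <- function(spec, stimulus) {
  stop_if_not(inherits(spec, "synthetic_neuron"), "spec must be a synthetic_neuron")
  info <- stim_info(stimulus)  # errors on unsampled input
  stop_if_not(nrow(stimulus) > 0, "unsampled stimulus")

  t <- stimulus$time_ms
  i <- stimulus$current_na
  dt <- info$sampling_interval_ms
  t_end <- t[length(t)] + dt

  spike_times <- synthetic_spike_times(spec, info, t_end)

  # passive subthreshold response: depolarization proportional to current,
  # capped at 60% of the gap to the 0 mV detection threshold so sub-rheobase
  # stimuli never cross it
  thr_gap <- max(0 - spec$resting_mv, 20)
  drive <- pmin(pmax(i, 0) / max(spec$rheobase_na, 1e-9), 1)
  v <- spec$resting_mv + 0.6 * thr_gap * drive * 0.67

  v <- insert_ap_waveforms(v, t, dt, spike_times, spec)

  if (spec$noise_sd > 0) {
    v <- v + with_seed(spec$seed + length(t), rnorm(length(t), sd = spec$noise_sd))
  }
  trace <- tibble(time_ms = t, voltage_mv = v)
  attr(trace, "stimulus") <- stimulus
  class(trace) <- c("voltage_trace", class(trace))
  trace
}

# analytic spike times for a synthetic neuron under one stimulus
synthetic_spike_times <- function(spec, info, t_end) {
  rb <- spec$rheobase_na

  if (spec$intrinsic_spiking) {
    ts <- seq(max(spec$delay_ms, 1), t_end, by = spec$isi_base_ms)
    return(ts)
  }
  kind <- info$kind
  onset <- info$onset_ms
  offset <- onset + info$duration_ms

  if (kind %in% c("square", "long_square")) {
    amp <- info$amplitude_na
    if (is.null(amp) || amp < rb || rb <= 0) return(numeric(0))
    scale <- (1.5 * rb) / amp
    ts <- onset + spec$delay_ms * scale
    isi <- spec$isi_base_ms * scale
    out <- c()
    while (ts < offset) {
      out <- c(out, ts)
      ts <- ts + isi
      isi <- isi * spec$accommodation_rate
    }
    return(out)
  }

  if (kind == "ramp") {
    slope <- info$slope_rb_per_s * info$rheobase_na / 1000  # nA/ms
    if (slope <= 0 || rb <= 0) return(numeric(0))
    ts <- onset + rb / slope      # current first reaches rheobase
    out <- c()
    k <- 0
    while (ts < offset) {
      out <- c(out, ts)
      i_now <- slope * (ts - onset)
      isi <- spec$isi_base_ms * (1.5 * rb / i_now) * spec$accommodation_rate^k
      ts <- ts + max(isi, 2 * spec$ap_width_ms)
      k <- k + 1
    }
    return(out)
  }

  if (kind %in% c("short_square", "short_square_triple")) {
    amp <- info$amplitude_na
    if (is.null(amp) || amp < rb || rb <= 0) return(numeric(0))
    if (kind == "short_square") return(onset + 1)
    spacing <- 1000 / info$pulse_frequency_hz
    pulses <- onset + (0:2) * spacing
    in_band <- is.null(spec$freq_band) ||
      (info$pulse_frequency_hz >= spec$freq_band[1] &&
         info$pulse_frequency_hz <= spec$freq_band[2])
    keep <- if (in_band) pulses else pulses[1]
    return(keep + 1)
  }

  numeric(0)  # pink_noise and zero stimuli: subthreshold only
}

# overwrite trace samples with a stylized AP at each spike time:
# instantaneous rise to peak at the spike time, linear fall back to resting
# over 2*width (so time above half-amplitude = width), then a linear AHP
# notch of depth ahp_depth_mv over 2*width
insert_ap_waveforms <- function(v, t, dt, spike_times, spec) {
  if (length(spike_times) == 0) return(v)
  peak <- spec$resting_mv + spec$ap_amplitude_mv
  w <- spec$ap_width_ms
  n <- length(v)
  for (ts in spike_times) {
    i0 <- ceiling(ts / dt - 1e-9) + 1L   # first sample at/after the spike time
    if (i0 > n) next
    fall_n <- max(1L, round(2 * w / dt))
    idx <- i0:min(n, i0 + fall_n - 1L)
    frac <- (seq_along(idx) - 1L) / fall_n
    v[idx] <- peak - (peak - spec$resting_mv) * frac
    ahp_n <- max(2L, round(2 * w / dt))
    a0 <- i0 + fall_n
    aidx <- a0:min(n, a0 + ahp_n - 1L)
    if (length(aidx) > 0 && a0 <= n) {
      af <- (seq_along(aidx) - 1L) / ahp_n
      v[aidx] <- spec$resting_mv - spec$ahp_depth_mv * (1 - af)
    }
  }
  v
}

#' Write / read voltage traces as delimited text
#'
#' @param trace A `voltage_trace` tibble.
#' @param path File path.
#' @return `path` invisibly, or the trace tibble for the reader.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[, c("time_ms", "voltage_mv")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  trace <- as_tibble(df)
  class(trace) <- c("voltage_trace", class(trace))
  trace
}
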