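#' Current-clamp stimulus protocols
#'
#' `build_protocol()` constructs a fully sampled stimulus waveform of one of
#' the kinds used to characterize cell models: `square` / `long_square`
#' (constant step), `ramp` (linearly increasing current), `pink_noise`
#' (1/f-spectrum noise), `short_square` (brief pulse) and
#' `short_square_triple` (three brief pulses at a set frequency).
#'
#' Conventions: time is milliseconds, current nanoamps, and all stimulus
#' intervals are half-open `[onset, onset + duration)`. The returned waveform
#' is a tibble with columns `time_ms` and `current_na`, sampled on
#' `[0, onset + duration + tail)`, carrying the protocol parameters as
#' attributes (see [stim_info()]).
#'
#' @param kind One of `"square"`, `"long_square"`, `"ramp"`, `"pink_noise"`,
#'   `"short_square"`, `"short_square_triple"`.
#' @param onset_ms Stimulus onset (ms), `>= 0`.
#' @param duration_ms Stimulus duration (ms), `> 0`. For
#'   `short_square_triple` this is the width of each individual pulse.
#' @param amplitude_na Current amplitude (nA). For `pink_noise` it is the
#'   standard deviation of the noise current; for `ramp` it is ignored (the
#'   ramp is defined by `slope_rb_per_s * rheobase_na`).
#' @param sampling_interval_ms Sampling interval (ms), `> 0`.
#' @param slope_rb_per_s Ramp slope in rheobase units per second (ramp only).
#' @param rheobase_na Rheobase current used to scale the ramp slope (ramp
#'   only).
#' @param pulse_frequency_hz Pulse frequency for `short_square_triple`; pulses
#'   are equally spaced at `1000 / pulse_frequency_hz` ms.
#' @param tail_ms Quiet recording window appended after the stimulus (ms).
#' @param seed Integer seed for `pink_noise` (required for that kind).
#' @return A `stimulus_waveform` tibble (`time_ms`, `current_na`).
#' @examples
#' sq <- build_protocol("square", onset_ms = 1000, duration_ms = 1000,
#'                      amplitude_na = 0.5)
#' stim_info(sq)$kind
#' @export
build_protocol <- function(kind,
                           onset_ms = 1000,
                           duration_ms = 1000,
                           amplitude_na = NULL,
                           sampling_interval_ms = 0.1,
                           slope_rb_per_s = NULL,
                           rheobase_na = NULL,
                           pulse_frequency_hz = NULL,
                           tail_ms = 500,
                           seed = NULL) {
  kinds <- c("square", "long_square", "ramp", "pink_noise",
             "short_square", "short_square_triple")
  stop_if_not(is.character(kind) && length(kind) == 1L && kind %in% kinds,
              paste0("unknown protocol kind: ", paste(kind, collapse = ",")))
  stop_if_not(is_number(onset_ms) && onset_ms >= 0, "onset_ms must be >= 0")
  stop_if_not(is_number(duration_ms) && duration_ms > 0,
              "duration_ms must be > 0")
  stop_if_not(is_number(sampling_interval_ms) && sampling_interval_ms > 0,
              "sampling_interval_ms must be > 0")

  dt <- sampling_interval_ms
  pulse_spacing <- NULL
  total <- onset_ms + duration_ms + tail_ms
  if (kind == "short_square_triple") {
    stop_if_not(is_number(pulse_frequency_hz) && pulse_frequency_hz > 0,
                "missing parameter: pulse_frequency_hz must be a positive number")
    pulse_spacing <- 1000 / pulse_frequency_hz
    total <- onset_ms + 2 * pulse_spacing + duration_ms + tail_ms
  }
  t <- seq(0, total - dt, by = dt)
  i <- numeric(length(t))
  during <- t >= onset_ms & t < onset_ms + duration_ms

  if (kind %in% c("square", "long_square", "short_square")) {
    stop_if_not(is_number(amplitude_na), "missing parameter: amplitude_na")
    i[during] <- amplitude_na
  } else if (kind == "ramp") {
    stop_if_not(is_number(slope_rb_per_s),
                "missing parameter: slope_rb_per_s")
    stop_if_not(is_number(rheobase_na),
                "missing parameter: rheobase_na")
    # slope in nA/ms: (rheobase units / s) * rheobase / 1000
    slope_na_per_ms <- slope_rb_per_s * rheobase_na / 1000
    i[during] <- slope_na_per_ms * (t[during] - onset_ms)
  } else if (kind == "pink_noise") {
    stop_if_not(is_number(amplitude_na), "missing parameter: amplitude_na")
    stop_if_not(!is.null(seed), "pink_noise requires a seed")
    n_during <- sum(during)
    i[during] <- with_seed(seed, pink_noise_samples(n_during)) * amplitude_na
  } else if (kind == "short_square_triple") {
    stop_if_not(is_number(amplitude_na), "missing parameter: amplitude_na")
    for (k in 0:2) {
      p0 <- onset_ms + k * pulse_spacing
      i[t >= p0 & t < p0 + duration_ms] <- amplitude_na
    }
  }

  wf <- tibble(time_ms = t, current_na = i)
  attr(wf, "stim") <- list(
    kind = kind, onset_ms = onset_ms, duration_ms = duration_ms,
    amplitude_na = amplitude_na, sampling_interval_ms = dt,
    slope_rb_per_s = slope_rb_per_s, rheobase_na = rheobase_na,
    pulse_frequency_hz = pulse_frequency_hz, tail_ms = tail_ms,
    seed = seed
  )
  class(wf) <- c("stimulus_waveform", class(wf))
  wf
}

#' Protocol parameters of a stimulus waveform
#'
#' @param stimulus A waveform built by [build_protocol()].
#' @return A named list of the protocol parameters.
#' @export
stim_info <- function(stimulus) {
  info <- attr(stimulus, "stim", exact = TRUE)
  stop_if_not(!is.null(info), "not a stimulus waveform (missing 'stim' attribute)")
  info
}

# unit-variance 1/f-spectrum noise via spectral shaping
pink_noise_samples <- function(n) {
  if (n < 2) return(numeric(n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # fold to two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Current series for the variable-timestep complexity benchmark
#'
#' Builds the 13-amplitude square-current series used to fit the
#' steps-vs-spikes linear model: 0 nA, the largest known sub-rheobase
#' current, and 11 evenly spaced amplitudes spanning
#' `[rheobase, 1.5 * rheobase]` inclusive.
#'
#' @param rheobase_na Rheobase current (nA), must be positive. A non-positive
#'   value signals an intrinsically spiking model, for which the complexity
#'   protocol is not applicable, and is an error here.
#' @param sub_rheobase_na Largest known sub-rheobase current (nA),
#'   `0 <= sub_rheobase_na < rheobase_na`. By convention this is the lower
#'   bisection bracket recorded by [find_rheobase()].
#' @return A `complexity_series` tibble with column `current_na` (13 rows)
#'   and attributes `rheobase_na`, `sub_rheobase_na`.
#' @examples
#' complexity_current_series(1, 0.9)$current_na
#' @export
complexity_current_series <- function(rheobase_na, sub_rheobase_na) {
  stop_if_not(is_number(rheobase_na) && rheobase_na > 0,
              "non-positive rheobase: complexity protocol not applicable")
  stop_if_not(is_number(sub_rheobase_na) &&
                sub_rheobase_na >= 0 && sub_rheobase_na < rheobase_na,
              "sub_rheobase_na must satisfy 0 <= sub < rheobase")
  supra <- seq(rheobase_na, 1.5 * rheobase_na, length.out = 11)
  out <- tibble(current_na = c(0, sub_rheobase_na, supra))
  attr(out, "rheobase_na") <- rheobase_na
  attr(out, "sub_rheobase_na") <- sub_rheobase_na
  class(out) <- c("complexity_series", class(out))
  out
}

#' Voltage-clamp protocols for channel model characterization
#'
#' Channel models are probed with three step protocols: `activation`
#' (depolarizing steps from a hyperpolarized holding potential),
#' `deactivation` (tail currents after a fixed activating pulse) and
#' `inactivation` (varying pre-pulse followed by a fixed test pulse).
#'
#' @param kind One of `"activation"`, `"deactivation"`, `"inactivation"`.
#' @param step_mv Voltages (mV) of the variable segment; defaults per kind.
#' @param hold_mv Holding potential (mV).
#' @param step_ms Duration of the variable segment (ms).
#' @param sampling_interval_ms Sampling interval (ms).
#' @return A `clamp_protocol` list describing the voltage-command segments.
#' @export
clamp_protocol <- function(kind = c("activation", "deactivation", "inactivation"),
                           step_mv = NULL,
                           hold_mv = -90,
                           step_ms = NULL,
                           sampling_interval_ms = 0.2) {
  kind <- match.arg(kind)
  defaults <- list(
    activation   = list(step_mv = seq(-70, 30, by = 20),  step_ms = 100),
    deactivation = list(step_mv = seq(-100, -40, by = 20), step_ms = 80),
    inactivation = list(step_mv = seq(-100, -20, by = 20), step_ms = 200)
  )
  step_mv <- step_mv %||% defaults[[kind]]$step_mv
  step_ms <- step_ms %||% defaults[[kind]]$step_ms
  stop_if_not(is.numeric(step_mv) && length(step_mv) >= 1,
              "step_mv must be a numeric vector")
  structure(
    list(kind = kind, step_mv = step_mv, hold_mv = hold_mv,
         step_ms = step_ms, hold_ms = 20,
         activating_mv = 20, activating_ms = 20,  # deactivation pre-pulse
         test_mv = 20, test_ms = 60,              # inactivation test pulse
         sampling_interval_ms = sampling_interval_ms),
    class = "clamp_protocol"
  )
}

#' The standard set of three voltage-clamp protocols
#' @inheritParams clamp_protocol
#' @return Named list of three [clamp_protocol()] objects.
#' @export
standard_clamp_protocols <- function(sampling_interval_ms = 0.2) {
  list(
    activation   = clamp_protocol("activation",
                                  sampling_interval_ms = sampling_interval_ms),
    deactivation = clamp_protocol("deactivation",
                                  sampling_interval_ms = sampling_interval_ms),
    inactivation = clamp_protocol("inactivation",
                                  sampling_interval_ms = sampling_interval_ms)
  )
}

#' Write a stimulus waveform as two-column delimited text
#'
#' @param stimulus A `stimulus_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(stimulus, path) {
  utils::write.table(stimulus[, c("time_ms", "current_na")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
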