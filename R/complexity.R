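#' Generate a synthetic integration step-count table
#'
#' Emulates the "baseline + per-spike" behaviour of a variable-timestep
#' integrator: the total number of steps to simulate 1 s is
#' `steps_base_true + steps_ap_true * APs`, optionally with Poisson counting
#' noise around that mean.
#'
#' @param steps_base_true True baseline steps per simulated second (`> 0`).
#' @param steps_ap_true True additional steps per action potential (`>= 0`).
#' @param series A [complexity_current_series()] (13 currents).
#' @param ap_counts Integer spike counts observed at each current (same
#'   length as `series`).
#' @param counting_noise `"none"` (exact rounded linear values) or
#'   `"poisson"` (Poisson draws with the linear value as mean).
#' @param seed Integer seed (Poisson noise only).
#' @return Tibble `current_na`, `ap_count`, `steps`.
#' @export
generate_step_count_table <- function(steps_base_true, steps_ap_true,
                                      series, ap_counts,
                                      counting_noise = c("none", "poisson"),
                                      seed = 1L) {
  counting_noise <- match.arg(counting_noise)
  stop_if_not(is_number(steps_base_true) && steps_base_true > 0,
              "steps_base_true must be > 0")
  stop_if_not(is_number(steps_ap_true) && steps_ap_true >= 0,
              "steps_ap_true must be >= 0")
  stop_if_not(length(ap_counts) == nrow(series),
              "length mismatch: ap_counts vs current series")
  mu <- steps_base_true + steps_ap_true * ap_counts
  steps <- if (counting_noise == "none") {
    round(mu)
  } else {
    with_seed(seed, rpois(length(mu), lambda = mu))
  }
  tibble(current_na = series$current_na,
         ap_count = as.integer(ap_counts),
         steps = as.numeric(steps))
}

#' Fit the linear steps-vs-spikes model
#'
#' Ordinary least squares of total integration steps against action-potential
#' count: the intercept is the baseline number of steps needed to compute 1 s
#' of simulation (`steps_base`) and the slope the mean additional steps per
#' action potential (`steps_ap`). A negative fitted slope is clamped to 0
#' with a warning.
#'
#' @param pairs Data frame with columns `ap_count` and `steps` (a table from
#'   [generate_step_count_table()] works directly).
#' @return A `step_model_fit` object; see [tidy()] / [glance()] methods.
#' @examples
#' fit_step_model(data.frame(ap_count = c(0, 5, 10),
#'                           steps = c(1000, 2000, 3000)))
#' @export
fit_step_model <- function(pairs) {
  stop_if_not(is.data.frame(pairs) &&
                all(c("ap_count", "steps") %in% names(pairs)),
              "pairs must have columns ap_count and steps")
  stop_if_not(nrow(pairs) >= 2, "need >= 2 points")
  stop_if_not(length(unique(pairs$ap_count)) >= 2,
              "slope unidentifiable: all AP counts identical")
  fit <- lm(steps ~ ap_count, data = pairs)
  cf <- coef(fit)
  slope <- unname(cf["ap_count"])
  if (slope < 0) {
    warn("negative fitted steps/AP slope clamped to 0")
    slope <- 0
  }
  structure(
    list(steps_base = unname(cf["(Intercept)"]),
         steps_ap = slope,
         fit_r2 = suppressWarnings(summary(fit)$r.squared),
         n_points = nrow(pairs),
         lm = fit),
    class = "step_model_fit"
  )
}

#' @export
print.step_model_fit <- function(x, ...) {
  cat("Variable-timestep step model fit\n")
  cat(sprintf("  steps_base: %.1f steps/s\n", x$steps_base))
  cat(sprintf("  steps_ap:   %.1f steps/AP\n", x$steps_ap))
  cat(sprintf("  r^2 = %.4f on %d points\n", x$fit_r2, x$n_points))
  invisible(x)
}

#' Absolute variable-timestep complexity
#'
#' The wall-clock time needed to simulate 1 s of model output containing
#' `target_rate` action potentials:
#' `omega_abs = (steps_base + steps_ap * target_rate) * runtime_step`.
#'
#' @param fit A [fit_step_model()] result.
#' @param runtime_step Measured mean wall-clock seconds per integration step
#'   (`> 0`); an input measurement, not computed here, so the estimate stays
#'   hardware-explicit.
#' @param target_rate Assumed firing rate (APs per simulated second).
#' @return A one-row `complexity_estimate` tibble: `steps_base`, `steps_ap`,
#'   `runtime_step`, `target_rate`, `omega_abs`.
#' @export
absolute_complexity <- function(fit, runtime_step, target_rate = 10) {
  stop_if_not(inherits(fit, "step_model_fit"), "fit must be a step_model_fit")
  stop_if_not(is_number(runtime_step) && runtime_step > 0,
              "non-positive runtime_step")
  stop_if_not(is_number(target_rate) && target_rate >= 0,
              "target_rate must be >= 0")
  out <- tibble(steps_base = fit$steps_base, steps_ap = fit$steps_ap,
                runtime_step = runtime_step, target_rate = target_rate,
                omega_abs = (fit$steps_base + fit$steps_ap * target_rate) *
                  runtime_step)
  class(out) <- c("complexity_estimate", class(out))
  out
}

#' Relative complexity in reference-model ("HH") units
#'
#' Divides the target model's absolute complexity by the reference model's;
#' by construction the reference model has relative complexity exactly 1.
#'
#' @param target,reference `complexity_estimate` rows from
#'   [absolute_complexity()].
#' @return Unitless ratio `target$omega_abs / reference$omega_abs`.
#' @export
relative_complexity <- function(target, reference) {
  stop_if_not(is.data.frame(reference) && is_number(reference$omega_abs) &&
                reference$omega_abs > 0,
              "reference omega_abs must be > 0")
  target$omega_abs / reference$omega_abs
}

#' Complexity report for a set of models
#'
#' @param fits Named list of `step_model_fit` objects.
#' @param runtime_steps Named numeric vector of seconds/step per model.
#' @param reference Name of the reference model (defines 1 HH).
#' @param target_rate Assumed firing rate.
#' @return Tibble `model_id`, `steps_base`, `steps_ap`, `omega_abs`,
#'   `omega_hh`.
#' @export
complexity_report <- function(fits, runtime_steps, reference,
                              target_rate = 10) {
  stop_if_not(reference %in% names(fits), "reference model not in fits")
  est <- purrr::imap_dfr(fits, function(f, id) {
    dplyr::mutate(
      absolute_complexity(f, runtime_steps[[id]], target_rate),
      model_id = id, .before = 1)
  })
  ref_abs <- est$omega_abs[est$model_id == reference]
  dplyr::mutate(est, omega_hh = .data$omega_abs / ref_abs)[
    , c("model_id", "steps_base", "steps_ap", "omega_abs", "omega_hh")]
}
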