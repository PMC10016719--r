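#' Ion-channel model specification with first-order gating kinetics
#'
#' Synthetic channel models follow first-order Boltzmann (in)activation
#' gating: the activation gate relaxes exponentially toward
#' `1 / (1 + exp(-(V - v_half) / k))` with time constant
#' `activation_tau_ms`; channels with an inactivation gate multiply in an
#' analogous (inverted) term. Families carry conventional defaults: Kv, KCa
#' (outward, non-inactivating), Nav, Cav (inward, inactivating), and Ih
#' (hyperpolarization-activated, inverted slope).
#'
#' @param family One of `"Kv"`, `"Nav"`, `"Cav"`, `"KCa"`, `"Ih"`.
#' @param activation_v_half Activation half-voltage (mV).
#' @param activation_tau_ms Activation time constant (ms, `> 0`).
#' @param activation_k Activation slope (mV; negative for Ih).
#' @param inactivation_v_half,inactivation_tau_ms,inactivation_k Optional
#'   inactivation gate parameters (`NA` = no inactivation).
#' @param reversal_mv Reversal potential (mV).
#' @return A `channel_spec` object.
#' @export
channel_family_spec <- function(family = c("Kv", "Nav", "Cav", "KCa", "Ih"),
                                activation_v_half = NULL,
                                activation_tau_ms = NULL,
                                activation_k = NULL,
                                inactivation_v_half = NULL,
                                inactivation_tau_ms = NULL,
                                inactivation_k = 6,
                                reversal_mv = NULL) {
  family <- match.arg(family)
  defaults <- list(
    Kv  = list(vh = -30, tau = 5,   k = 5,  ivh = NA,  itau = NA, rev = -85),
    Nav = list(vh = -35, tau = 0.5, k = 5,  ivh = -60, itau = 2,  rev = 50),
    Cav = list(vh = -20, tau = 2,   k = 5,  ivh = -40, itau = 50, rev = 120),
    KCa = list(vh = -10, tau = 10,  k = 5,  ivh = NA,  itau = NA, rev = -85),
    Ih  = list(vh = -80, tau = 50,  k = -8, ivh = NA,  itau = NA, rev = -30)
  )[[family]]
  tau <- activation_tau_ms %||% defaults$tau
  itau <- inactivation_tau_ms %||% defaults$itau
  stop_if_not(is_number(tau) && tau > 0, "activation_tau_ms must be > 0")
  if (!is.na(itau %||% NA)) {
    stop_if_not(is_number(itau) && itau > 0, "inactivation_tau_ms must be > 0")
  }
  structure(
    list(family = family,
         activation_v_half = activation_v_half %||% defaults$vh,
         activation_tau_ms = tau,
         activation_k = activation_k %||% defaults$k,
         inactivation_v_half = inactivation_v_half %||% defaults$ivh,
         inactivation_tau_ms = itau %||% NA_real_,
         inactivation_k = inactivation_k,
         reversal_mv = reversal_mv %||% defaults$rev),
    class = "channel_spec")
}

boltzmann <- function(v, vh, k) 1 / (1 + exp(-(v - vh) / k))

# piecewise-constant voltage command => piecewise-exponential gate relaxation
gate_trajectory <- function(v_seg, dur_seg, dt, vh, k, tau, inverted = FALSE) {
  inf_of <- function(v) {
    m <- boltzmann(v, vh, k)
    if (inverted) 1 - m else m
  }
  state <- inf_of(v_seg[1])   # equilibrated at the first (holding) segment
  out_t <- out_v <- out_g <- numeric(0)
  t0 <- 0
  for (s in seq_along(v_seg)) {
    tt <- seq(0, dur_seg[s] - dt, by = dt)
    target <- inf_of(v_seg[s])
    g <- target + (state - target) * exp(-tt / tau)
    state <- target + (state - target) * exp(-dur_seg[s] / tau)
    out_t <- c(out_t, t0 + tt)
    out_v <- c(out_v, rep(v_seg[s], length(tt)))
    out_g <- c(out_g, g)
    t0 <- t0 + dur_seg[s]
  }
  list(time_ms = out_t, command_mv = out_v, gate = out_g)
}

# voltage-command segments of one protocol step
clamp_segments <- function(protocol, step_v) {
  switch(protocol$kind,
    activation = list(v = c(protocol$hold_mv, step_v),
                      dur = c(protocol$hold_ms, protocol$step_ms)),
    deactivation = list(
      v = c(protocol$hold_mv, protocol$activating_mv, step_v),
      dur = c(protocol$hold_ms, protocol$activating_ms, protocol$step_ms)),
    inactivation = list(
      v = c(protocol$hold_mv, step_v, protocol$test_mv),
      dur = c(protocol$hold_ms, protocol$step_ms, protocol$test_ms)))
}

#' Voltage-clamp responses of synthetic channel models
#'
#' Simulates each channel specification under each clamp protocol
#' (activation, deactivation, inactivation) with closed-form first-order
#' gating, returning the input voltage command alongside the output
#' conductance and current for every voltage step.
#'
#' @param specs Named list of [channel_family_spec()] objects (names become
#'   `model_id`s).
#' @param protocols Named list of [clamp_protocol()] objects covering the
#'   three protocol kinds (see [standard_clamp_protocols()]).
#' @return Tibble: `model_id`, `family`, `protocol`, `step_mv`, `time_ms`,
#'   `command_mv`, `conductance`, `current`.
#' @export
generate_channel_response_set <- function(specs,
                                          protocols = standard_clamp_protocols()) {
  kinds <- vapply(protocols, `[[`, character(1), "kind")
  missing <- setdiff(c("activation", "deactivation", "inactivation"), kinds)
  stop_if_not(length(missing) == 0,
              paste0("missing protocol kind: ", paste(missing, collapse = ", ")))
  ids <- names(specs) %||% paste0("channel_", seq_along(specs))
  purrr::map2_dfr(specs, ids, function(spec, id) {
    purrr::map_dfr(protocols, function(pr) {
      dt <- pr$sampling_interval_ms
      purrr::map_dfr(pr$step_mv, function(sv) {
        seg <- clamp_segments(pr, sv)
        m <- gate_trajectory(seg$v, seg$dur, dt, spec$activation_v_half,
                             spec$activation_k, spec$activation_tau_ms)
        g <- m$gate
        if (!is.na(spec$inactivation_v_half)) {
          h <- gate_trajectory(seg$v, seg$dur, dt, spec$inactivation_v_half,
                               spec$inactivation_k, spec$inactivation_tau_ms,
                               inverted = TRUE)
          g <- g * h$gate
        }
        tibble(model_id = id, family = spec$family, protocol = pr$kind,
               step_mv = sv, time_ms = m$time_ms, command_mv = m$command_mv,
               conductance = g,
               current = g * (m$command_mv - spec$reversal_mv) / 1000)
      })
    })
  })
}

#' Channel model sets with planted kinetic archetypes
#'
#' Builds `n_archetypes` kinetic archetypes of one family — randomly placed
#' activation half-voltages (roughly `shift_mv` apart) with systematically
#' scaled time constants — and populates each archetype with a
#' seed-dependent number of member models (between `n_per_range[1]` and
#' `n_per_range[2]`). By default members are exact copies of their
#' archetype, emulating how sub-types arise in model databases through model
#' reuse; `jitter_mv > 0` adds per-member kinetic variation instead.
#'
#' @param family Channel family.
#' @param n_archetypes Number of archetypes (`>= 2`).
#' @param n_per_range Range of members per archetype (inclusive).
#' @param shift_mv Half-voltage spacing between archetypes (mV).
#' @param jitter_mv SD of per-member half-voltage jitter (mV); 0 = exact
#'   copies.
#' @param seed Integer seed.
#' @return List: `specs` (named list), `truth` (tibble `model_id`,
#'   `archetype`).
#' @export
generate_channel_archetype_set <- function(family = "Kv", n_archetypes = 3,
                                           n_per_range = c(4, 10),
                                           shift_mv = 25,
                                           jitter_mv = 0, seed = 1L) {
  base <- channel_family_spec(family)
  with_seed(seed, {
    centered <- seq_len(n_archetypes) - (n_archetypes + 1) / 2
    offsets <- centered * shift_mv + rnorm(n_archetypes, sd = shift_mv / 6)
    tau_scale <- 3^centered * exp(rnorm(n_archetypes, sd = 0.2))
    # distinct member counts: sub-type prevalences in model databases differ,
    # and the typicality-based scores resolve equally prevalent exact-copy
    # archetypes only through their prevalence
    stop_if_not(diff(n_per_range) + 1 >= n_archetypes,
                "n_per_range too narrow for distinct archetype sizes")
    n_per <- sample(seq(n_per_range[1], n_per_range[2]), n_archetypes,
                    replace = FALSE)
    specs <- list()
    truth_a <- integer(0)
    for (a in seq_len(n_archetypes)) {
      for (i in seq_len(n_per[a])) {
        specs[[length(specs) + 1L]] <- channel_family_spec(
          family,
          activation_v_half = base$activation_v_half + offsets[a] +
            rnorm(1, sd = jitter_mv),
          activation_tau_ms = base$activation_tau_ms * tau_scale[a])
        truth_a <- c(truth_a, a)
      }
    }
    ids <- sprintf("%s_%02d", tolower(family), seq_along(specs))
    names(specs) <- ids
    list(specs = specs, truth = tibble(model_id = ids, archetype = truth_a))
  })
}
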