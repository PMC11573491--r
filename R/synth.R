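#' Specification of a synthetic dataset
#'
#' Bundles every parameter of the behavioral and neural generators so a
#' whole synthetic study is reproducible from one object and one seed.
#'
#' Behavioral side: a softmax agent ([agent_policy()]) run through the task
#' simulator. Neural side: an inhomogeneous-Poisson population whose
#' per-neuron baseline rates are gamma-distributed around `baseline_rate`
#' and whose peri-choice rate profile follows one of two condition
#' templates — `"stable"` (constant pre-choice drive, the short-delay,
#' procedural regime) or `"ramping"` (linear rise over the last
#' `ramp_onset_s`..0 s before the choice, the long-delay, deliberative
#' regime). On the fourth trial of the targeted run types (Change runs by
#' default), a random subset of `prop_affected` of the neurons receives an
#' extra rate offset of `delta` Hz — constant in the stable regime, rising
#' from zero at ramp onset to `delta` at the choice in the ramping regime —
#' planting a known Change-versus-Fail-to-Change signal whose magnitude is
#' controlled by `delta`.
#'
#' @param k_true Agent discount rate (1/s).
#' @param temperature Softmax inverse-noise (1/pellets).
#' @param a Delayed amount (pellets).
#' @param n_neurons Number of synthetic neurons.
#' @param baseline_rate Mean baseline firing rate (Hz).
#' @param template `"stable"` or `"ramping"`.
#' @param delta Rate offset (Hz) added on trial 4 of the targeted run types
#'   in the affected subset; `delta = 0` plants no signal.
#' @param prop_affected Fraction of neurons receiving the offset.
#' @param affected_types Run types whose fourth trial receives the offset.
#'   Both Change types by default (deliberative regime); set to
#'   `"DEL-Change"` alone to emulate the short-delay regime where only
#'   switches away from the preferred delay lever carry an update signal.
#' @param ramp_onset_s Ramp onset relative to the choice (s, negative).
#' @param ramp_gain Peak multiplicative gain of the ramp template.
#' @param seed Master seed for all generators reading this spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(k_true = 0.3, temperature = 3, a = 6,
                       n_neurons = 40, baseline_rate = 5,
                       template = c("stable", "ramping"),
                       delta = 0, prop_affected = 0.3,
                       affected_types = c("IM-Change", "DEL-Change"),
                       ramp_onset_s = -8, ramp_gain = 1,
                       seed = 1) {
  template <- match.arg(template)
  stopifnot(baseline_rate >= 0, delta >= 0, n_neurons >= 1,
            prop_affected >= 0, prop_affected <= 1, ramp_onset_s < 0)
  structure(
    list(
      k_true = k_true, temperature = temperature, a = a,
      n_neurons = as.integer(n_neurons), baseline_rate = baseline_rate,
      template = template, delta = delta, prop_affected = prop_affected,
      affected_types = affected_types,
      ramp_onset_s = ramp_onset_s, ramp_gain = ramp_gain,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> agent k=%g/s beta=%g; %d neurons @ %g Hz, %s template, delta=%g Hz, seed=%d\n",
    x$k_true, x$temperature, x$n_neurons, x$baseline_rate,
    x$template, x$delta, x$seed
  ))
  invisible(x)
}

#' Generate synthetic behavioral sessions across delays
#'
#' Simulates `n_sessions` task sessions at each delay with the spec's agent.
#' Session seeds are derived deterministically from the spec seed.
#'
#' @param spec A [synth_spec()].
#' @param delays Delay conditions in seconds.
#' @param n_sessions Sessions per delay.
#' @param max_choice_trials,max_duration_s Session termination parameters
#'   (30 trials / 35 min standard; 40 / 45 min for the recording variant).
#' @param seed Overrides `spec$seed`.
#' @return A trial tibble covering all sessions (see [simulate_session()]),
#'   with `session_id` of the form `d<delay>_s<rep>`.
#' @export
generate_behavior <- function(spec, delays = c(0, 1, 2, 4, 8, 16),
                              n_sessions = 1,
                              max_choice_trials = 30,
                              max_duration_s = 35 * 60,
                              seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  pol <- agent_policy(spec$k_true, spec$a, spec$temperature)
  grid <- tidyr::expand_grid(delay_s = delays, rep = seq_len(n_sessions))
  sub_seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1L, nrow(grid)))
  purrr::pmap_dfr(
    list(grid$delay_s, grid$rep, sub_seeds),
    function(d, r, s) {
      simulate_session(
        pol, d,
        max_choice_trials = max_choice_trials,
        max_duration_s = max_duration_s,
        session_id = sprintf("d%g_s%d", d, r),
        seed = s
      )
    }
  )
}

#' Synthetic run-event schedule
#'
#' Builds an event table with a prescribed number of runs per run type,
#' spacing choice events so peri-choice windows never overlap. Useful for
#' driving [generate_spikes()] and [per_session_distances()] with a known
#' run composition.
#'
#' @param n_per_type Runs per run type.
#' @param types Run types to include.
#' @param gap_s Time between the third- and fourth-trial choices of a run.
#' @param start_s Time of the first choice event.
#' @return An event tibble compatible with [run_events()] output.
#' @export
synth_run_events <- function(n_per_type = 3,
                             types = c("IM-Change", "IM-FtC", "DEL-Change", "DEL-FtC"),
                             gap_s = 30, start_s = 25) {
  grid <- tidyr::expand_grid(run_type = types, rep = seq_len(n_per_type))
  events <- grid |>
    dplyr::mutate(run_id = dplyr::row_number()) |>
    tidyr::expand_grid(position = c(3L, 4L)) |>
    dplyr::arrange(.data$run_id, .data$position) |>
    dplyr::mutate(
      session_id = "synth",
      lever = sub("-.*", "", .data$run_type),
      outcome = ifelse(grepl("FtC", .data$run_type), "Fail-to-Change", "Change"),
      t_choice = start_s + gap_s * (dplyr::row_number() - 1),
      trial_index = dplyr::row_number()
    )
  dplyr::select(
    events, "session_id", "run_id", "run_type", "lever", "outcome",
    "position", "trial_index", "t_choice"
  )
}

# Baseline template g(t) over times relative to the choice: 1 for the stable
# regime; rising linearly from 1 at ramp onset to 1 + gain at the choice
# (and held after it) for the ramping regime.
template_shape <- function(t_rel, template, ramp_onset_s, ramp_gain) {
  if (template == "stable") {
    rep(1, length(t_rel))
  } else {
    1 + ramp_gain * ramp_frac(t_rel, ramp_onset_s)
  }
}

ramp_frac <- function(t_rel, ramp_onset_s) {
  pmin(pmax((t_rel - ramp_onset_s) / (0 - ramp_onset_s), 0), 1)
}

# Shape of the planted Change-trial offset: the stable regime carries a
# constant pattern shift, the ramping regime one that grows from zero at
# ramp onset to its full value at the choice, emulating evidence
# accumulation toward the decision.
offset_shape <- function(t_rel, template, ramp_onset_s) {
  if (template == "stable") rep(1, length(t_rel)) else ramp_frac(t_rel, ramp_onset_s)
}

#' Generate synthetic spike trains around run events
#'
#' Inhomogeneous-Poisson spikes for `spec$n_neurons` neurons around every
#' event in `events`. Each neuron's baseline is drawn once from a gamma
#' distribution (shape 4) around `spec$baseline_rate`; the peri-event rate
#' is baseline x template shape; on the fourth trial of the targeted run
#' types a fixed random subset of neurons additionally receives an offset of
#' `spec$delta` Hz — constant under the stable template, growing from zero
#' at ramp onset to `delta` at the choice under the ramping template.
#' Spikes are emitted per fine time step (50 ms) and jittered
#' uniformly within the step. All randomness derives from one seed.
#'
#' @param spec A [synth_spec()].
#' @param events Event table ([run_events()] / [synth_run_events()]).
#' @param window Time span around each event in which spikes are generated;
#'   slightly wider than the analysis window by default so smoothing has
#'   real data at the edges.
#' @param dt Fine time step (s) of the Poisson discretization.
#' @param seed Overrides `spec$seed`.
#' @return A list: `spikes` (tibble `neuron_id`, `spike_time`, sorted),
#'   `affected` (ids of the offset subset), `baseline` (per-neuron rates).
#' @export
generate_spikes <- function(spec, events, window = c(-21, 3), dt = 0.05,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  stopifnot(all(c("run_type", "position", "t_choice") %in% names(events)))
  with_seed_if(seed, {
    n <- spec$n_neurons
    base <- stats::rgamma(n, shape = 4, rate = 4 / spec$baseline_rate)
    n_aff <- round(spec$prop_affected * n)
    affected <- sort(sample.int(n, n_aff))

    t_rel <- seq(window[1], window[2] - dt, by = dt)
    g <- template_shape(t_rel + dt / 2, spec$template, spec$ramp_onset_s, spec$ramp_gain)
    off <- offset_shape(t_rel + dt / 2, spec$template, spec$ramp_onset_s)
    is_target4 <- events$run_type %in% spec$affected_types & events$position == 4L

    out <- vector("list", nrow(events) * n)
    idx <- 0L
    for (e in seq_len(nrow(events))) {
      for (nn in seq_len(n)) {
        rate <- base[nn] * g
        if (is_target4[e] && nn %in% affected) {
          rate <- rate + spec$delta * off
        }
        counts <- stats::rpois(length(t_rel), rate * dt)
        tot <- sum(counts)
        if (tot > 0) {
          times <- rep(t_rel, counts) + stats::runif(tot, 0, dt)
          idx <- idx + 1L
          out[[idx]] <- tibble::tibble(
            neuron_id = nn,
            spike_time = events$t_choice[e] + times
          )
        }
      }
    }
    spikes <- dplyr::bind_rows(out[seq_len(idx)]) |>
      dplyr::filter(.data$spike_time >= 0) |>
      dplyr::arrange(.data$neuron_id, .data$spike_time)
    list(spikes = spikes, affected = affected, baseline = base)
  })
}
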