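#' Construct a softmax agent policy for the adjusting-amount task
#'
#' The agent assigns the immediate lever its current payout (`i` pellets,
#' delivered with no delay) and the delay lever the hyperbolically
#' discounted value of the fixed delayed reward, `a / (1 + k_true * d)`.
#' Choices are drawn from a logistic softmax over the difference of the two
#' subjective values.
#'
#' @param k_true True discount rate of the agent, in 1/seconds. `k_true = 0`
#'   means no discounting (the delayed reward keeps its full value).
#' @param a Fixed number of pellets delivered by the delay lever (6 in the
#'   task this package models).
#' @param temperature Softmax inverse-noise parameter (1/pellets). Larger
#'   values make the agent more deterministic; `Inf` gives a greedy agent
#'   that breaks exact value ties in favor of the delay lever.
#' @param seed Optional integer seed used by [simulate_session()] when no
#'   explicit seed is passed.
#'
#' @return An object of class `agent_policy`.
#' @examples
#' agent_policy(k_true = 0.3, temperature = 3)
#' @export
agent_policy <- function(k_true, a = 6, temperature = 5, seed = NULL) {
  stopifnot(is.numeric(k_true), length(k_true) == 1, k_true >= 0)
  stopifnot(is.numeric(a), length(a) == 1, a > 0)
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("`temperature` must be a single positive number (Inf allowed).")
  }
  structure(
    list(k_true = k_true, a = a, temperature = temperature, seed = seed),
    class = "agent_policy"
  )
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(
    sprintf(
      "<agent_policy> k_true = %g /s, a = %g pellets, temperature = %g\n",
      x$k_true, x$a, x$temperature
    )
  )
  invisible(x)
}

#' Update the immediate-lever payout after a choice trial
#'
#' The immediate (adjusting) lever dispenses 0--6 pellets. A delay choice
#' increases the payout by one pellet on the next trial, an immediate choice
#' decreases it by one, clamped to the 0--6 range. Forced trials do not pass
#' through this function: they leave the i-value unchanged.
#'
#' @param i Current i-value(s), integer in 0..6.
#' @param choice `"delay"` or `"immediate"` (recycled against `i`).
#'
#' @return Updated integer i-value(s).
#' @examples
#' update_i_value(3, "delay")      # 4
#' update_i_value(0, "immediate")  # 0, clamped
#' @export
update_i_value <- function(i, choice) {
  choice <- match_lever(choice)
  if (!is.numeric(i) || any(is.na(i)) || any(i != round(i)) || any(i < 0) || any(i > 6)) {
    stop("invalid i-value state: `i` must be an integer in [0, 6].")
  }
  out <- ifelse(choice == "delay", pmin(i + 1, 6), pmax(i - 1, 0))
  as.integer(out)
}

#' Decide whether the next trial is a choice or a forced trial
#'
#' Two consecutive same-lever responses on choice trials trigger a forced
#' trial on the other lever. A forced trial resets the consecutive-choice
#' counter, so only choice trials *after* the most recent forced trial are
#' considered. An omitted forced trial is repeated; the simulator never
#' omits, but the rule holds for recorded data where an omission appears as
#' a forced trial with no response.
#'
#' @param trials A data frame of prior trials with columns `kind`
#'   (`"choice"`/`"forced"`) and `chosen_lever` (`"immediate"`/`"delay"`,
#'   `NA` for an omitted forced trial). May have zero rows.
#'
#' @return A one-row tibble with columns `kind` (`"choice"` or `"forced"`)
#'   and `forced_lever` (`"immediate"`, `"delay"`, or `"none"`).
#' @examples
#' h <- tibble::tibble(kind = c("choice", "choice"),
#'                     chosen_lever = c("immediate", "immediate"))
#' next_trial_kind(h)  # forced trial on the delay lever
#' @export
next_trial_kind <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    return(tibble::tibble(kind = "choice", forced_lever = "none"))
  }
  stopifnot(all(c("kind", "chosen_lever") %in% names(trials)))
  last <- nrow(trials)
  if (trials$kind[last] == "forced" && is.na(trials$chosen_lever[last])) {
    # omitted forced trial: repeat it
    return(tibble::tibble(kind = "forced", forced_lever = trials$forced_lever[last]))
  }
  last_forced <- max(c(0L, which(trials$kind == "forced")))
  recent <- trials$chosen_lever[trials$kind == "choice" &
    seq_len(nrow(trials)) > last_forced]
  n <- length(recent)
  if (n >= 2 && recent[n] == recent[n - 1]) {
    other <- if (recent[n] == "immediate") "delay" else "immediate"
    return(tibble::tibble(kind = "forced", forced_lever = other))
  }
  tibble::tibble(kind = "choice", forced_lever = "none")
}

#' Simulate one adjusting-amount delay discounting session
#'
#' Runs the within-session task: the i-value starts at 3 pellets, each delay
#' choice increments and each immediate choice decrements it by one (clamped
#' to 0..6), two consecutive same-lever choices force a trial on the other
#' lever, and the session ends after `max_choice_trials` choice trials or
#' `max_duration_s` seconds, whichever comes first. Forced trials do not
#' change the i-value.
#'
#' Trial timing follows the task structure: a 10 s house-light period opens
#' each trial, levers extend for initiation, retract for 1 s and re-extend
#' for the choice. Choice latencies are drawn from a log-normal whose median
#' scales inversely with the absolute subjective-value difference, so hard
#' (close-value) decisions are slow — this supports latency-contrast
#' analyses downstream.
#'
#' @param policy An [agent_policy()].
#' @param delay_s Delay of the delay lever in seconds (0, 1, 2, 4, 8 or 16
#'   in the task; any nonnegative value is accepted).
#' @param max_choice_trials Session ends after this many choice trials
#'   (30 standard; 40 for the longer recording variant).
#' @param max_duration_s Session ends after this many seconds
#'   (2100 s = 35 min standard; 2700 s = 45 min for the recording variant).
#' @param session_id Identifier stored with every trial.
#' @param laser Laser condition label stored with every trial
#'   (`"off"`, `"on"`, or `"n/a"`).
#' @param seed Integer seed; falls back to `policy$seed`. Two calls with the
#'   same seed return identical sessions.
#'
#' @return A tibble with one row per trial: `session_id`, `trial_index`,
#'   `kind`, `forced_lever`, `chosen_lever`, `i_value`, `delay_s`, `laser`,
#'   `t_house_light`, `t_initiation`, `t_choice`, `t_reward`,
#'   `choice_latency` (timestamps in seconds from session start).
#' @examples
#' pol <- agent_policy(k_true = 0.3, temperature = 3)
#' ses <- simulate_session(pol, delay_s = 8, seed = 1)
#' head(ses)
#' @export
simulate_session <- function(policy, delay_s,
                             max_choice_trials = 30,
                             max_duration_s = 35 * 60,
                             session_id = "S1",
                             laser = c("off", "on", "n/a"),
                             seed = policy$seed) {
  stopifnot(inherits(policy, "agent_policy"))
  stopifnot(is.numeric(delay_s), length(delay_s) == 1, delay_s >= 0)
  stopifnot(max_choice_trials >= 1, max_duration_s > 0)
  laser <- match.arg(laser)
  with_seed_if(seed, simulate_session_impl(
    policy, delay_s, max_choice_trials, max_duration_s, session_id, laser
  ))
}

simulate_session_impl <- function(policy, delay_s, max_choice_trials,
                                  max_duration_s, session_id, laser) {
  a <- policy$a
  beta <- policy$temperature
  v_del <- a / (1 + policy$k_true * delay_s)

  house_light_s <- 10
  retract_s <- 1
  iti_s <- 10
  lat_sdlog <- 0.4

  rows <- list()
  i <- 3L
  t <- 0
  n_choice <- 0L

  while (t < max_duration_s && n_choice < max_choice_trials) {
    hist_df <- if (length(rows)) dplyr::bind_rows(rows) else NULL
    nxt <- next_trial_kind(hist_df)
    kind <- nxt$kind
    forced_lever <- nxt$forced_lever

    v_imm <- i
    dv <- v_del - v_imm
    if (kind == "forced") {
      lever <- forced_lever
      lat_median <- 0.5
    } else {
      p_delay <- if (is.infinite(beta)) as.numeric(dv >= 0) else stats::plogis(beta * dv)
      lever <- if (stats::runif(1) < p_delay) "delay" else "immediate"
      lat_median <- 1 / (abs(dv) + 0.25)
    }
    latency <- stats::rlnorm(1, meanlog = log(lat_median), sdlog = lat_sdlog)

    t_house <- t
    t_init <- t_house + house_light_s + stats::rlnorm(1, log(0.5), 0.3)
    t_choice <- t_init + retract_s + latency
    t_reward <- t_choice + if (lever == "delay") delay_s else 0
    t_reward <- t_reward + 0.1 # pellet dispensing

    rows[[length(rows) + 1L]] <- tibble::tibble(
      session_id = session_id,
      trial_index = length(rows) + 1L,
      kind = kind,
      forced_lever = forced_lever,
      chosen_lever = lever,
      i_value = i,
      delay_s = delay_s,
      laser = laser,
      t_house_light = t_house,
      t_initiation = t_init,
      t_choice = t_choice,
      t_reward = t_reward,
      choice_latency = latency
    )

    if (kind == "choice") {
      n_choice <- n_choice + 1L
      i <- update_i_value(i, lever)
    }
    t <- t_reward + iti_s
  }
  dplyr::bind_rows(rows)
}

match_lever <- function(x) {
  if (!all(x %in% c("immediate", "delay"))) {
    stop('lever must be "immediate" or "delay".')
  }
  x
}
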