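# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with the simplest possible algorithm, not the package's.

# i-value trajectory under a choice sequence, one step at a time.
oracle_i_trajectory <- function(choices, start = 3) {
  i <- start
  out <- integer(length(choices))
  for (t in seq_along(choices)) {
    i <- if (choices[t] == "delay") min(i + 1, 6) else max(i - 1, 0)
    out[t] <- i
  }
  out
}

# Explicit state machine for the forced-trial rule: streak counts consecutive
# same-lever choice trials since the last forced trial.
oracle_next_kind <- function(kinds, levers) {
  streak_lever <- NA_character_
  streak <- 0L
  for (t in seq_along(kinds)) {
    if (kinds[t] == "forced") {
      streak <- 0L
      streak_lever <- NA_character_
    } else if (!is.na(streak_lever) && levers[t] == streak_lever) {
      streak <- streak + 1L
    } else {
      streak_lever <- levers[t]
      streak <- 1L
    }
  }
  if (streak >= 2) {
    list(kind = "forced",
         lever = if (streak_lever == "immediate") "delay" else "immediate")
  } else {
    list(kind = "choice", lever = "none")
  }
}

# Run segmentation by direct scan over a lever sequence ("immediate"/"delay"):
# a run starts wherever three equal levers begin a maximal streak; its fourth
# trial is the next choice position, and it is dropped if none exists.
oracle_segment <- function(lev) {
  n <- length(lev)
  out <- list()
  i <- 1L
  for (i in seq_len(max(0L, n - 2L))) {
    starts_streak <- lev[i] == lev[i + 1] && lev[i] == lev[i + 2] &&
      (i == 1L || lev[i - 1] != lev[i])
    if (!starts_streak) next
    len <- 3L
    while (i + len <= n && lev[i + len] == lev[i]) len <- len + 1L
    pos4 <- i + 3L
    if (pos4 > n) next
    out[[length(out) + 1L]] <- data.frame(
      lever = if (lev[i] == "immediate") "IM" else "DEL",
      start_choice_index = i,
      length = len,
      outcome = if (lev[pos4] == lev[i]) "Fail-to-Change" else "Change",
      pos3 = i + 2L,
      pos4 = pos4
    )
  }
  do.call(rbind, out)
}

# Benjamini-Yekutieli step-up adjustment written from the definition.
oracle_by <- function(p) {
  n <- length(p)
  cm <- sum(1 / seq_len(n))
  o <- order(p)
  adj <- pmin(1, cm * n / seq_len(n) * p[o])
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Choice-trial tibble from a lever sequence (plus optional forced inserts).
trials_from_levers <- function(levers, kinds = rep("choice", length(levers)),
                               session_id = "s1") {
  tibble::tibble(
    session_id = session_id,
    trial_index = seq_along(levers),
    kind = kinds,
    forced_lever = ifelse(kinds == "forced", levers, "none"),
    chosen_lever = levers,
    i_value = 3L,
    t_choice = 10 * seq_along(levers)
  )
}

# Wrap a plain array as an aligned tensor for unit tests that construct
# rate data directly.
make_tensor <- function(arr, window = c(-15, 15), bin_width = 0.2) {
  structure(
    arr,
    window = window, bin_width = bin_width,
    time = window[1] + bin_width * (seq_len(dim(arr)[2]) - 1),
    neuron_ids = seq_len(dim(arr)[1]),
    events = rep(0, dim(arr)[3]),
    truncated = rep(FALSE, dim(arr)[3]),
    smoothing = "none",
    class = c("aligned_tensor", "array")
  )
}

# All binary lever sequences of a given length, as a list.
all_lever_seqs <- function(len) {
  lapply(seq_len(2^len) - 1L, function(code) {
    bits <- as.integer(intToBits(code)[seq_len(len)])
    c("immediate", "delay")[bits + 1L]
  })
}
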