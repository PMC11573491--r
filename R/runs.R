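#' Segment the choice trials of a session into runs
#'
#' A run is three or more consecutive choice-trial responses on the same
#' lever; forced trials are ignored for continuity. Runs are maximal and
#' anchored: each maximal same-lever streak of length L >= 3 yields exactly
#' one run, anchored at its first three choices. The run's "trial 3" is the
#' third choice of the streak and "trial 4" is the next choice trial after
#' it (even if forced trials intervene). A run whose fourth choice trial
#' switches lever is a `Change` run; one that stays is `Fail-to-Change`.
#' A run reaching the end of the session without a fourth choice trial
#' cannot be classified and is dropped with a message.
#'
#' @param trials A trial table (one or more sessions).
#' @return A tibble with one row per classified run: `session_id`, `run_id`,
#'   `lever` (`"IM"`/`"DEL"`), `start_choice_index` (position within the
#'   session's choice-trial sequence), `length` (streak length),
#'   `outcome` (`"Change"`/`"Fail-to-Change"`), `trial3_index`,
#'   `trial4_index` (values of `trial_index` in `trials`).
#' @examples
#' tr <- tibble::tibble(
#'   session_id = "s", trial_index = 1:4, kind = "choice",
#'   chosen_lever = c("delay", "delay", "delay", "immediate")
#' )
#' segment_runs(tr)  # one DEL run, outcome Change
#' @export
segment_runs <- function(trials) {
  stopifnot(all(c("session_id", "trial_index", "kind", "chosen_lever") %in% names(trials)))
  parts <- split(seq_len(nrow(trials)), trials$session_id)
  out <- lapply(names(parts), function(sid) {
    one <- segment_runs_one(trials[parts[[sid]], , drop = FALSE])
    if (nrow(one)) one$session_id <- sid
    one
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(
      session_id = character(0), run_id = integer(0), lever = character(0),
      start_choice_index = integer(0), length = integer(0),
      outcome = character(0), trial3_index = integer(0),
      trial4_index = integer(0)
    ))
  }
  out$run_id <- seq_len(nrow(out))
  dplyr::relocate(out, "session_id", "run_id")
}

segment_runs_one <- function(trials) {
  empty <- tibble::tibble(
    lever = character(0), start_choice_index = integer(0),
    length = integer(0), outcome = character(0),
    trial3_index = integer(0), trial4_index = integer(0)
  )
  ord <- order(trials$trial_index)
  is_choice <- trials$kind[ord] == "choice"
  lev <- trials$chosen_lever[ord][is_choice]
  idx <- trials$trial_index[ord][is_choice]
  n <- length(lev)
  if (n < 3) return(empty)
  r <- rle(lev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$lengths >= 3)
  if (!length(keep)) return(empty)

  pos4 <- starts[keep] + 3L
  open <- pos4 > n
  if (any(open)) {
    message(sprintf(
      "run starting at choice %d has no fourth choice trial; excluded.",
      starts[keep][open]
    ))
    keep <- keep[!open]
    pos4 <- pos4[!open]
    if (!length(keep)) return(empty)
  }
  tibble::tibble(
    lever = ifelse(r$values[keep] == "immediate", "IM", "DEL"),
    start_choice_index = as.integer(starts[keep]),
    length = as.integer(r$lengths[keep]),
    outcome = ifelse(lev[pos4] == r$values[keep], "Fail-to-Change", "Change"),
    trial3_index = as.integer(idx[starts[keep] + 2L]),
    trial4_index = as.integer(idx[pos4])
  )
}

#' Label the eight run trial types
#'
#' Each classified run contributes two analyzed trials (the third and
#' fourth), giving eight trial types:
#' lever (IM/DEL) x outcome (Change/Fail-to-Change) x position (3/4).
#'
#' @param lever `"IM"` or `"DEL"` (vectorized).
#' @param outcome `"Change"` or `"Fail-to-Change"` (vectorized).
#' @param which Trial position within the run, 3 or 4 (vectorized).
#' @return Character labels such as `"DEL-Change-T3"` or `"IM-FtC-T4"`.
#' @export
trial_type_label <- function(lever, outcome, which) {
  if (!all(lever %in% c("IM", "DEL"))) stop('`lever` must be "IM" or "DEL".')
  if (!all(outcome %in% c("Change", "Fail-to-Change"))) {
    stop('`outcome` must be "Change" or "Fail-to-Change" (classified runs only).')
  }
  if (!all(which %in% c(3, 4))) stop("`which` must be 3 or 4.")
  paste0(lever, "-", ifelse(outcome == "Change", "Change", "FtC"), "-T", which)
}

#' All eight run trial-type labels
#'
#' @return Character vector of the 8 labels in a fixed order.
#' @export
trial_types <- function() {
  as.vector(outer(
    c("IM-Change", "IM-FtC", "DEL-Change", "DEL-FtC"),
    c("-T3", "-T4"), paste0
  ))
}

#' Run trials as alignable events
#'
#' Expands a runs table into one row per analyzed trial (positions 3 and 4)
#' with the run type and the choice timestamp, the event table consumed by
#' the ensemble analysis.
#'
#' @param trials Trial table with `trial_index` and `t_choice`.
#' @param runs Runs table from [segment_runs()]; defaults to segmenting
#'   `trials`.
#' @return A tibble: `session_id`, `run_id`, `run_type` (lever-outcome,
#'   e.g. `"DEL-Change"`), `lever`, `outcome`, `position` (3/4),
#'   `trial_index`, `t_choice`.
#' @export
run_events <- function(trials, runs = segment_runs(trials)) {
  stopifnot(all(c("trial_index", "t_choice") %in% names(trials)))
  if (!nrow(runs)) {
    return(tibble::tibble(
      session_id = character(0), run_id = integer(0), run_type = character(0),
      lever = character(0), outcome = character(0), position = integer(0),
      trial_index = integer(0), t_choice = numeric(0)
    ))
  }
  runs |>
    tidyr::pivot_longer(
      cols = c("trial3_index", "trial4_index"),
      names_to = "position", values_to = "trial_index"
    ) |>
    dplyr::mutate(
      position = ifelse(.data$position == "trial3_index", 3L, 4L),
      run_type = paste0(.data$lever, "-",
        ifelse(.data$outcome == "Change", "Change", "FtC"))
    ) |>
    dplyr::left_join(
      dplyr::select(trials, "session_id", "trial_index", "t_choice"),
      by = c("session_id", "trial_index")
    ) |>
    dplyr::select(
      "session_id", "run_id", "run_type", "lever", "outcome",
      "position", "trial_index", "t_choice"
    )
}
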