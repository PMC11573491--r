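#' Read and write trial tables
#'
#' Sessions are stored as plain CSV with one row per trial and the
#' documented column set (`session_id`, `trial_index`, `kind`,
#' `forced_lever`, `chosen_lever`, `i_value`, `delay_s`, `laser`,
#' `t_house_light`, `t_initiation`, `t_choice`, `t_reward`,
#' `choice_latency`), or as JSON (array of trial objects).
#'
#' @param trials A trial tibble.
#' @param path File path (`.csv` or `.json`).
#' @return `write_session()` returns `trials` invisibly; `read_session()`
#'   returns a trial tibble.
#' @export
write_session <- function(trials, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(trials, path, auto_unbox = FALSE, digits = NA)
  } else {
    readr::write_csv(trials, path)
  }
  invisible(trials)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read and write spike tables
#'
#' Spike tables are CSV files with columns `neuron_id` and `spike_time`
#' (seconds, ascending within neuron).
#'
#' @param spikes A spike tibble.
#' @param path CSV file path.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(all(c("neuron_id", "spike_time") %in% names(spikes)))
  readr::write_csv(spikes, path)
  invisible(spikes)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Persist an aligned tensor as tidy CSV plus JSON metadata
#'
#' The tensor is flattened to long form (`neuron_id`, `trial`, `bin`,
#' `rate`) in `<path>.csv`; window, bin width, smoothing descriptor, event
#' times and truncation flags go to `<path>.json`. [read_aligned_tensor()]
#' restores the array and its attributes.
#'
#' @param tensor An `aligned_tensor`.
#' @param path Path stem (extensions are appended).
#' @export
write_aligned_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  d <- dim(tensor)
  long <- tibble::tibble(
    neuron_id = rep(attr(tensor, "neuron_ids"), times = d[2] * d[3]),
    bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    rate = as.vector(tensor)
  )
  readr::write_csv(long, paste0(path, ".csv"))
  meta <- list(
    window = attr(tensor, "window"),
    bin_width = attr(tensor, "bin_width"),
    smoothing = attr(tensor, "smoothing"),
    events = attr(tensor, "events"),
    truncated = attr(tensor, "truncated"),
    neuron_ids = attr(tensor, "neuron_ids"),
    dim = d
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(tensor)
}

#' @rdname write_aligned_tensor
#' @export
read_aligned_tensor <- function(path) {
  long <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  d <- as.integer(meta$dim)
  arr <- array(long$rate, dim = d,
               dimnames = list(neuron = as.character(meta$neuron_ids), bin = NULL, trial = NULL))
  structure(
    arr,
    window = as.numeric(meta$window), bin_width = as.numeric(meta$bin_width),
    time = bin_centers(as.numeric(meta$window), as.numeric(meta$bin_width)),
    neuron_ids = meta$neuron_ids, events = as.numeric(meta$events),
    truncated = as.logical(meta$truncated),
    smoothing = as.character(meta$smoothing),
    class = c("aligned_tensor", "array")
  )
}
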