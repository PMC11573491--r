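#' Build a population state space over run trial types
#'
#' The per-trial-type, trial-averaged firing-rate matrices (time bins in
#' rows, neurons in columns) are stacked row-wise — eight 101-bin matrices
#' give an 808-row matrix — z-scored per neuron (population SD) over the
#' concatenated bins, and decomposed with PCA (via singular value
#' decomposition; the matrix is already column-centered by the z-scoring).
#' Component sign is fixed by forcing each component's largest-magnitude
#' loading positive, making the decomposition deterministic.
#'
#' @param mats Named list of matrices, one per trial type, each
#'   `bins x neurons` with identical dimensions and neuron order.
#' @param n_components Number of leading components returned as trajectory
#'   coordinates (3 by default).
#' @param ddof Delta degrees of freedom for the z-scoring SD.
#' @return An object of class `state_space`: `$scores` (tibble of
#'   `trial_type`, `bin`, `time` when available, `PC1..PCn`),
#'   `$scores_matrix` (all components, rows match the concatenated matrix),
#'   `$loadings` (neurons x components), `$explained_variance` (fraction per
#'   component, summing to 1), `$trial_types`, `$n_bins`,
#'   `$dropped_neurons`, `$zscored` (the concatenated z-scored matrix).
#' @export
build_state_space <- function(mats, n_components = 3, ddof = 0) {
  stopifnot(is.list(mats), length(mats) >= 1)
  nb <- unique(vapply(mats, nrow, integer(1)))
  nn <- unique(vapply(mats, ncol, integer(1)))
  if (length(nb) != 1 || length(nn) != 1) {
    stop("all trial-type matrices must share dimensions (bins x neurons).")
  }
  types <- names(mats) %||% paste0("type", seq_along(mats))
  x <- do.call(rbind, mats)

  mu <- colMeans(x)
  sdv <- apply(x, 2, sd_ddof, ddof = ddof)
  keep <- !is.na(sdv) & sdv > 0
  dropped <- colnames(x)[!keep] %||% which(!keep)
  if (!all(keep)) {
    message(sprintf("dropping %d zero-variance neuron(s) before PCA.", sum(!keep)))
  }
  if (sum(keep) < 3) stop("at least 3 neurons with variance are required for PCA.")
  xz <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")

  dec <- svd(xz)
  scores <- dec$u %*% diag(dec$d, nrow = length(dec$d))
  loadings <- dec$v
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- dec$d^2 / sum(dec$d^2)
  k <- min(n_components, ncol(scores))

  score_tbl <- tibble::as_tibble(
    scores[, seq_len(k), drop = FALSE],
    .name_repair = ~ paste0("PC", seq_len(k))
  ) |>
    dplyr::mutate(
      trial_type = rep(types, each = nb),
      bin = rep(seq_len(nb), times = length(mats)),
      .before = 1
    )
  rownames(loadings) <- colnames(x)[keep]
  structure(
    list(
      scores = score_tbl,
      scores_matrix = scores,
      loadings = loadings,
      explained_variance = ev,
      trial_types = types,
      n_bins = nb,
      n_components = k,
      dropped_neurons = if (length(dropped)) dropped else NULL,
      zscored = xz
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "<state_space> %d trial types x %d bins, %d neurons; top %d PCs explain %.1f%% of variance\n",
    length(x$trial_types), x$n_bins, nrow(x$loadings), x$n_components,
    100 * sum(x$explained_variance[seq_len(x$n_components)])
  ))
  invisible(x)
}

#' Extract a trial type's trajectory coordinates
#'
#' @param ss A `state_space`.
#' @param trial_type One of `ss$trial_types`.
#' @return A `bins x n_components` matrix of component scores.
#' @export
get_trajectory <- function(ss, trial_type) {
  stopifnot(inherits(ss, "state_space"))
  if (!trial_type %in% ss$trial_types) {
    stop("unknown trial type: ", trial_type)
  }
  ss$scores |>
    dplyr::filter(.data$trial_type == !!trial_type) |>
    dplyr::arrange(.data$bin) |>
    dplyr::select(dplyr::starts_with("PC")) |>
    as.matrix()
}

#' Per-bin Euclidean distance between two trajectories
#'
#' The diagonal of the full pairwise distance matrix between two
#' equally-long trajectories: at each time bin, the Euclidean norm of the
#' difference between the two coordinate vectors.
#'
#' @param traj3,traj4 Matrices `bins x components` with equal dimensions
#'   (typically the third- and fourth-trial trajectories of a run type).
#' @return A `distance_series` tibble with columns `bin` and `distance` and
#'   a `mean_distance` attribute (the Fig-style summary: mean over bins).
#' @examples
#' trajectory_distance(matrix(0, 1, 3), matrix(c(3, 4, 0), 1))  # 5
#' @export
trajectory_distance <- function(traj3, traj4) {
  traj3 <- as.matrix(traj3)
  traj4 <- as.matrix(traj4)
  if (!all(dim(traj3) == dim(traj4))) {
    stop("trajectories must have identical dimensions.")
  }
  vals <- sqrt(rowSums((traj3 - traj4)^2))
  out <- tibble::tibble(bin = seq_along(vals), distance = vals)
  attr(out, "mean_distance") <- mean(vals)
  class(out) <- c("distance_series", class(out))
  out
}

#' Mean over bins of a distance series
#' @param x A `distance_series`.
#' @return Scalar mean distance.
#' @export
mean_distance <- function(x) {
  attr(x, "mean_distance") %||% mean(x$distance)
}

#' Session-level trajectory distances between trials 3 and 4 of runs
#'
#' Runs the full per-session ensemble recipe: neurons failing the firing
#' criterion in any run trial-type category are excluded
#' ([filter_firing_neurons()]); spikes are aligned to the choice of the
#' third and fourth trials of each run type, binned (200 ms over -19..+1 s,
#' 101 bins), smoothed with a 5-bin moving average, and trial-averaged into
#' one `bins x neurons` matrix per trial type; matrices are concatenated,
#' z-scored and decomposed ([build_state_space()]); and the per-bin
#' Euclidean distance between each run type's third- and fourth-trial
#' trajectories is returned. Run types absent from the session are reported
#' as absent, never imputed.
#'
#' @param spikes Spike table for the session (`neuron_id`, `spike_time`).
#' @param events Event table from [run_events()] or
#'   [synth_run_events()] (`run_type`, `position`, `t_choice`).
#' @param window,bin_width Peri-choice window (s) and bin width (s).
#' @param span Moving-average span in bins.
#' @param n_components Number of leading PCs for the trajectories.
#' @return An object of class `session_distances`: `$distances` (tibble of
#'   `run_type`, `bin`, `time`, `distance`), `$summary` (tibble of
#'   `run_type`, `mean_distance`), `$state_space`, `$retention` (neuron
#'   bookkeeping), `$absent_types` (run types with no classified run).
#' @export
per_session_distances <- function(spikes, events, window = c(-19, 1),
                                  bin_width = 0.2, span = 5,
                                  n_components = 3) {
  if (!nrow(events)) stop("no classified runs supplied.")
  present <- sort(unique(events$run_type))
  absent <- setdiff(c("IM-Change", "IM-FtC", "DEL-Change", "DEL-FtC"), present)
  if (length(absent)) {
    message("run types absent from this session: ", paste(absent, collapse = ", "))
  }

  filt <- filter_firing_neurons(spikes, events, window)
  if (length(filt$neuron_ids) < 3) {
    stop("fewer than 3 neurons pass the firing criterion.")
  }
  time <- bin_centers(window, bin_width)

  cats <- events |>
    dplyr::mutate(category = paste0(.data$run_type, "-T", .data$position)) |>
    dplyr::group_by(.data$category) |>
    dplyr::group_split()
  mats <- lapply(cats, function(cat) {
    tens <- align_and_bin(spikes, cat$t_choice, window, bin_width,
                          neuron_ids = filt$neuron_ids)
    tens <- smooth_rates(tens, "moving_average", span = span)
    t(apply(tens, c(1, 2), mean)) # bins x neurons
  })
  names(mats) <- vapply(cats, function(cat) cat$category[1], character(1))

  ss <- build_state_space(mats, n_components = n_components)

  dist_tbl <- purrr::map_dfr(present, function(ty) {
    ds <- trajectory_distance(
      get_trajectory(ss, paste0(ty, "-T3")),
      get_trajectory(ss, paste0(ty, "-T4"))
    )
    tibble::tibble(run_type = ty, bin = ds$bin, time = time, distance = ds$distance)
  })
  summary <- dist_tbl |>
    dplyr::group_by(.data$run_type) |>
    dplyr::summarise(mean_distance = mean(.data$distance), .groups = "drop")

  structure(
    list(
      distances = dist_tbl, summary = summary, state_space = ss,
      retention = filt$summary, absent_types = absent
    ),
    class = "session_distances"
  )
}

#' @export
print.session_distances <- function(x, ...) {
  cat("<session_distances>\n")
  print(x$summary)
  if (length(x$absent_types)) {
    cat("absent run types:", paste(x$absent_types, collapse = ", "), "\n")
  }
  invisible(x)
}
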