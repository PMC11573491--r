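#' Number of peri-event time bins
#'
#' Inclusive-endpoint convention: bins are centered on a grid from the
#' window start to its end in steps of `bin_width`, so
#' `n = round((end - start) / bin_width) + 1`. A (-15, +15) s window at
#' 200 ms gives 151 bins; (-19, +1) s gives 101 bins.
#'
#' @param window Length-2 numeric `(start, end)` in seconds relative to the
#'   alignment event.
#' @param bin_width Bin width in seconds (0.2 by default).
#' @return Integer bin count.
#' @examples
#' bin_count(c(-15, 15))  # 151
#' bin_count(c(-19, 1))   # 101
#' @export
bin_count <- function(window, bin_width = 0.2) {
  stopifnot(length(window) == 2)
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be positive.")
  if (window[2] <= window[1]) stop("window end must exceed its start.")
  as.integer(round((window[2] - window[1]) / bin_width) + 1)
}

#' Centers of the peri-event time bins
#'
#' @inheritParams bin_count
#' @return Numeric vector of bin centers (s relative to the event).
#' @export
bin_centers <- function(window, bin_width = 0.2) {
  window[1] + bin_width * (seq_len(bin_count(window, bin_width)) - 1)
}

#' Align spike trains to events and bin into firing rates
#'
#' For every neuron and event, spikes are counted in `bin_width`-wide bins
#' centered on the grid returned by [bin_centers()] and converted to rates
#' (counts / bin width, Hz). Events whose window extends before the start of
#' the recording (time 0) or past `recording_end_s` are flagged as
#' truncated.
#'
#' @param spikes A tibble with columns `neuron_id` and `spike_time`
#'   (seconds, nonnegative).
#' @param events Numeric vector of event (e.g. choice) times in seconds.
#' @param window,bin_width Peri-event window and bin width, seconds.
#' @param neuron_ids Optional vector fixing the neuron set and order;
#'   defaults to the sorted unique ids in `spikes`. Ids without spikes get
#'   all-zero rows.
#' @param recording_end_s Optional recording end used for truncation flags.
#' @return An `aligned_tensor`: a 3-D array `neurons x bins x trials` of
#'   firing rates with attributes `window`, `bin_width`, `time` (bin
#'   centers), `neuron_ids`, `events`, `truncated`, `smoothing`.
#' @export
align_and_bin <- function(spikes, events, window = c(-19, 1), bin_width = 0.2,
                          neuron_ids = NULL, recording_end_s = NULL) {
  stopifnot(all(c("neuron_id", "spike_time") %in% names(spikes)))
  if (length(events) == 0) stop("`events` is empty; nothing to align to.")
  if (any(spikes$spike_time < 0)) stop("spike times must be nonnegative.")
  neuron_ids <- neuron_ids %||% sort(unique(spikes$neuron_id))
  nb <- bin_count(window, bin_width)
  centers <- bin_centers(window, bin_width)
  edges <- c(centers - bin_width / 2, centers[nb] + bin_width / 2)

  by_neuron <- split(spikes$spike_time, factor(spikes$neuron_id, levels = neuron_ids))
  arr <- array(
    0,
    dim = c(length(neuron_ids), nb, length(events)),
    dimnames = list(neuron = as.character(neuron_ids), bin = NULL, trial = NULL)
  )
  for (j in seq_along(events)) {
    for (k in seq_along(neuron_ids)) {
      rel <- by_neuron[[k]] - events[j]
      rel <- rel[rel >= edges[1] & rel < edges[nb + 1]]
      if (length(rel)) {
        idx <- findInterval(rel, edges, rightmost.closed = FALSE)
        arr[k, , j] <- arr[k, , j] + tabulate(idx, nbins = nb)
      }
    }
  }
  arr <- arr / bin_width
  truncated <- events + window[1] < 0
  if (!is.null(recording_end_s)) {
    truncated <- truncated | (events + window[2] > recording_end_s)
  }
  structure(
    arr,
    window = window, bin_width = bin_width, time = centers,
    neuron_ids = neuron_ids, events = events, truncated = truncated,
    smoothing = "none",
    class = c("aligned_tensor", "array")
  )
}

#' @export
print.aligned_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<aligned_tensor> %d neurons x %d bins x %d trials; window [%g, %g] s, bin %g s, smoothing: %s\n",
    d[1], d[2], d[3], attr(x, "window")[1], attr(x, "window")[2],
    attr(x, "bin_width"), attr(x, "smoothing")
  ))
  invisible(x)
}

smoothing_kernel <- function(method, bin_width, span, sigma) {
  if (method == "moving_average") {
    if (span %% 2 == 0) stop("`span` must be odd.")
    rep(1 / span, span)
  } else {
    half <- max(1L, ceiling(4 * sigma / bin_width))
    offs <- (-half:half) * bin_width
    w <- stats::dnorm(offs, 0, sigma)
    w / sum(w)
  }
}

convolve_reflect <- function(x, kernel) {
  half <- (length(kernel) - 1) / 2
  n <- length(x)
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  as.numeric(stats::filter(padded, kernel, sides = 2))[half + seq_len(n)]
}

#' Smooth peri-event firing rates along time
#'
#' Per-neuron (and per-trial) smoothing along the time-bin axis, either a
#' boxcar moving average (default: 5 bins, the setting used for binned
#' population analyses) or Gaussian convolution (default sigma = 10 ms on
#' the 200 ms bin grid). Edges are handled by reflected padding, so a
#' constant series is left unchanged.
#'
#' @param x An `aligned_tensor` or a neurons x bins matrix.
#' @param method `"moving_average"` or `"gaussian"`.
#' @param span Moving-average span in bins (odd).
#' @param sigma Gaussian kernel standard deviation in seconds.
#' @param bin_width Bin width in seconds; taken from the tensor attributes
#'   when `x` is an `aligned_tensor`.
#' @return Same shape and class as `x`, with an updated `smoothing`
#'   attribute for tensors.
#' @export
smooth_rates <- function(x, method = c("moving_average", "gaussian"),
                         span = 5, sigma = 0.01, bin_width = NULL) {
  method <- match.arg(method)
  is_tensor <- inherits(x, "aligned_tensor")
  bw <- if (is_tensor) attr(x, "bin_width") else bin_width %||% 0.2
  kernel <- smoothing_kernel(method, bw, span, sigma)
  nb <- if (is.matrix(x)) ncol(x) else dim(x)[2]
  if (length(kernel) > nb) stop("smoothing kernel is longer than the time series.")

  if (is.matrix(x)) {
    out <- t(apply(x, 1, convolve_reflect, kernel = kernel))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  out <- x
  for (j in seq_len(dim(x)[3])) {
    out[, , j] <- t(apply(x[, , j, drop = TRUE] |> matrix(nrow = dim(x)[1]),
                          1, convolve_reflect, kernel = kernel))
  }
  attr(out, "smoothing") <- if (method == "moving_average") {
    sprintf("moving_average(%d bins)", span)
  } else {
    sprintf("gaussian(sigma=%g s)", sigma)
  }
  out
}

#' Z-score firing rates per neuron
#'
#' Each neuron's rates are standardized to mean 0 and standard deviation 1
#' over all its bins (concatenated across trials for a 3-D tensor). The
#' population standard deviation (`ddof = 0`) is the default. Neurons with
#' zero variance carry no signal and are dropped with a message; their ids
#' are recorded in the `dropped_neurons` attribute.
#'
#' @param x An `aligned_tensor` or a neurons x bins matrix.
#' @param ddof Delta degrees of freedom for the standard deviation
#'   (0 = population, 1 = sample).
#' @return Same type as `x` with zero-variance neurons removed.
#' @export
zscore_rates <- function(x, ddof = 0) {
  is_tensor <- inherits(x, "aligned_tensor")
  dims <- dim(x)
  flat <- if (is.matrix(x)) x else matrix(x, nrow = dims[1]) # neurons x (bins*trials)
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, sd_ddof, ddof = ddof)
  keep <- !is.na(sdv) & sdv > 0
  if (!all(keep)) {
    ids <- if (is_tensor) attr(x, "neuron_ids") else rownames(x) %||% seq_len(nrow(flat))
    message(sprintf("dropping %d zero-variance neuron(s).", sum(!keep)))
    dropped <- ids[!keep]
  } else {
    dropped <- NULL
  }
  flat <- (flat[keep, , drop = FALSE] - mu[keep]) / sdv[keep]

  if (is.matrix(x)) {
    out <- flat
    rownames(out) <- rownames(x)[keep]
    attr(out, "dropped_neurons") <- dropped
    return(out)
  }
  out_arr <- array(flat, dim = c(sum(keep), dims[2], dims[3]))
  attrs <- attributes(x)
  attrs$dim <- dim(out_arr)
  attrs$dimnames <- NULL
  attrs$neuron_ids <- attrs$neuron_ids[keep]
  attributes(out_arr) <- attrs
  attr(out_arr, "dropped_neurons") <- dropped
  out_arr
}

#' Condition-averaged firing rates with per-timepoint FDR tests
#'
#' Computes the grand-average (over neurons) firing-rate trace per choice
#' condition (IM/DEL x low/high i-value) and runs paired t tests across
#' neurons at every time bin for the two within-lever contrasts
#' (IM-low vs IM-high, DEL-low vs DEL-high), with Benjamini--Yekutieli FDR
#' correction across bins within each contrast.
#'
#' @param tensor An `aligned_tensor` (typically smoothed and z-scored),
#'   trials in the third dimension.
#' @param labels Character vector, one label per trial, with values in
#'   `"IM-low"`, `"IM-high"`, `"DEL-low"`, `"DEL-high"`.
#' @param alpha Significance level applied to the adjusted p values.
#' @return An object of class `condition_averages`: `$averages` (tibble of
#'   `condition`, `bin`, `time`, `mean`, `sem`) and `$tests` (tibble of
#'   `contrast`, `bin`, `time`, `statistic`, `p_raw`, `p_adjusted`,
#'   `significant`).
#' @export
condition_averages <- function(tensor, labels, alpha = 0.05) {
  stopifnot(inherits(tensor, "aligned_tensor"))
  conditions <- c("IM-low", "IM-high", "DEL-low", "DEL-high")
  if (!all(labels %in% conditions)) {
    stop("`labels` must be IM-low / IM-high / DEL-low / DEL-high.")
  }
  if (length(labels) != dim(tensor)[3]) {
    stop("one label per trial is required.")
  }
  counts <- table(factor(labels, levels = conditions))
  if (any(counts < 2)) {
    stop("every condition needs at least 2 trials; missing/near-empty: ",
         paste(conditions[counts < 2], collapse = ", "))
  }
  time <- attr(tensor, "time")
  nb <- dim(tensor)[2]

  # neurons x bins mean per condition (average over that condition's trials)
  per_cond <- lapply(conditions, function(cn) {
    sel <- which(labels == cn)
    apply(tensor[, , sel, drop = FALSE], c(1, 2), mean)
  })
  names(per_cond) <- conditions

  averages <- purrr::map_dfr(conditions, function(cn) {
    m <- per_cond[[cn]]
    tibble::tibble(
      condition = cn, bin = seq_len(nb), time = time,
      mean = colMeans(m),
      sem = apply(m, 2, stats::sd) / sqrt(nrow(m))
    )
  })

  contrast_test <- function(name, c1, c2) {
    stat <- p <- numeric(nb)
    for (b in seq_len(nb)) {
      x <- per_cond[[c1]][, b]
      y <- per_cond[[c2]][, b]
      if (sd_ddof(x - y, 1) %in% c(0, NA)) {
        stat[b] <- 0
        p[b] <- 1
      } else {
        tt <- stats::t.test(x, y, paired = TRUE)
        stat[b] <- unname(tt$statistic)
        p[b] <- tt$p.value
      }
    }
    adj <- fdr_by(p)
    tibble::tibble(
      contrast = name, bin = seq_len(nb), time = time,
      statistic = stat, p_raw = p, p_adjusted = adj,
      significant = adj < alpha
    )
  }
  tests <- dplyr::bind_rows(
    contrast_test("IM-low vs IM-high", "IM-low", "IM-high"),
    contrast_test("DEL-low vs DEL-high", "DEL-low", "DEL-high")
  )
  structure(list(averages = averages, tests = tests, alpha = alpha),
            class = "condition_averages")
}

#' @export
print.condition_averages <- function(x, ...) {
  nsig <- x$tests |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(n_significant = sum(.data$significant))
  cat("<condition_averages>\n")
  print(nsig)
  invisible(x)
}

#' Neurons firing in every run trial-type category
#'
#' Population analyses include only neurons that fire at least one spike
#' within the peri-choice window of the third and the fourth trial of every
#' run type present in the data. Spike counts are totalled across the
#' trials of each (run type x position) category.
#'
#' @param spikes Spike table (`neuron_id`, `spike_time`).
#' @param events Event table from [run_events()] (needs `run_type`,
#'   `position`, `t_choice`).
#' @param window Peri-choice window in seconds.
#' @param neuron_ids Optional neuron universe; defaults to ids in `spikes`.
#' @return A list: `neuron_ids` (retained), `summary` (one-row tibble
#'   `starting`, `excluded`, `retained`), `by_category` (logical matrix
#'   neurons x categories of the firing criterion).
#' @export
filter_firing_neurons <- function(spikes, events, window = c(-19, 1),
                                  neuron_ids = NULL) {
  neuron_ids <- neuron_ids %||% sort(unique(spikes$neuron_id))
  cats <- events |>
    dplyr::group_by(.data$run_type, .data$position) |>
    dplyr::group_split()
  fired <- vapply(cats, function(cat) {
    counts <- rep(0, length(neuron_ids))
    names(counts) <- as.character(neuron_ids)
    for (t0 in cat$t_choice) {
      sel <- spikes$spike_time >= t0 + window[1] & spikes$spike_time <= t0 + window[2]
      tb <- table(factor(spikes$neuron_id[sel], levels = neuron_ids))
      counts <- counts + as.numeric(tb)
    }
    counts > 0
  }, logical(length(neuron_ids)))
  fired <- matrix(fired, nrow = length(neuron_ids))
  rownames(fired) <- as.character(neuron_ids)
  colnames(fired) <- vapply(
    cats, function(cat) paste0(cat$run_type[1], "-T", cat$position[1]), character(1)
  )
  keep <- rowSums(!fired) == 0
  list(
    neuron_ids = neuron_ids[keep],
    summary = retention_table(length(neuron_ids), sum(!keep)),
    by_category = fired
  )
}
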