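#' Hyperbolic subjective value of a delayed reward
#'
#' `v = a / (1 + k * d)`: the subjective value of `a` pellets delivered after
#' a delay of `d` seconds under discount rate `k` (1/s).
#'
#' @param d Delay(s) in seconds.
#' @param k Discount rate, 1/seconds, `k >= 0`.
#' @param a Amount of the delayed reward in pellets.
#' @return Subjective value in pellets.
#' @export
hyperbolic_value <- function(d, k, a = 6) {
  a / (1 + k * d)
}

#' Indifference point of a single session
#'
#' Mean i-value over the last `n_last` choice trials of the session; forced
#' trials are excluded. The i-value oscillates around the point where the
#' immediate and delayed options are equally attractive, so this tail
#' average estimates the indifference point in pellets.
#'
#' @param trials A trial table from [simulate_session()] (or read from CSV)
#'   containing a single session.
#' @param n_last Number of final choice trials to average (10 by default).
#' @return The indifference point in pellets (scalar).
#' @seealso [indifference_points()] for a per-session table across sessions.
#' @export
indifference_point <- function(trials, n_last = 10) {
  if (length(unique(trials$session_id)) > 1) {
    stop("`trials` contains more than one session; use indifference_points().")
  }
  choice <- trials$i_value[trials$kind == "choice"]
  if (length(choice) < n_last) {
    stop(sprintf(
      "session has %d choice trials; %d required for the indifference point.",
      length(choice), n_last
    ))
  }
  mean(utils::tail(choice, n_last))
}

#' Indifference points for every session in a trial table
#'
#' @inheritParams indifference_point
#' @return A tibble with one row per session: `session_id`, `delay_s`,
#'   `laser`, `indifference_point`.
#' @export
indifference_points <- function(trials, n_last = 10) {
  trials |>
    dplyr::group_by(.data$session_id, .data$delay_s, .data$laser) |>
    dplyr::group_modify(function(d, key) {
      d$session_id <- "only"
      tibble::tibble(indifference_point = indifference_point(d, n_last))
    }) |>
    dplyr::ungroup()
}

#' Fit the hyperbolic discounting model to indifference points
#'
#' Least-squares fit of `v(d) = a / (1 + k d)` to indifference points across
#' delays, with the discount rate constrained to `k >= 0`. The fit is a
#' deterministic bounded one-dimensional search: a log-spaced grid over
#' `[0, k_max]` brackets the minimum, which is then refined with
#' [stats::optimize()].
#'
#' @param data Data frame with columns `delay_s` (seconds) and
#'   `indifference_point` (pellets); one row per delay (or per
#'   session x delay).
#' @param a Fixed delayed amount in pellets.
#' @param k_max Upper bound of the search interval (1/s).
#' @return An object of class `mazur_fit` with elements `k`, `sse`, `a`,
#'   `data` (augmented with fitted values), `n`. Supports [tidy()],
#'   [glance()], `predict()` and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(delay_s = c(0, 1, 2, 4, 8, 16),
#'                     indifference_point = 6 / (1 + 0.5 * c(0, 1, 2, 4, 8, 16)))
#' fit <- fit_mazur(d)
#' fit$k
#' @export
fit_mazur <- function(data, a = 6, k_max = 100) {
  stopifnot(all(c("delay_s", "indifference_point") %in% names(data)))
  d <- data$delay_s
  ip <- data$indifference_point
  if (length(unique(d)) < 2) {
    stop("at least 2 distinct delays are required to fit the discount rate.")
  }
  fit <- fit_k_ls(d, ip, a, k_max)
  out <- list(
    k = fit$k, sse = fit$sse, a = a,
    data = dplyr::mutate(tibble::as_tibble(data),
      fitted = hyperbolic_value(.data$delay_s, fit$k, a)
    ),
    n = length(ip)
  )
  class(out) <- "mazur_fit"
  out
}

# Deterministic constrained 1-D least squares for the discount rate.
fit_k_ls <- function(d, ip, a, k_max = 100) {
  sse <- function(k) sum((ip - a / (1 + k * d))^2)
  grid <- c(0, 10^seq(-4, log10(k_max), length.out = 40))
  vals <- vapply(grid, sse, numeric(1))
  j <- which.min(vals)
  lo <- grid[max(1L, j - 1L)]
  hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  cand_k <- c(0, grid[j], opt$minimum)
  cand_sse <- c(vals[1], vals[j], opt$objective)
  best <- which.min(cand_sse)
  list(k = cand_k[best], sse = cand_sse[best])
}

#' @export
print.mazur_fit <- function(x, ...) {
  cat(sprintf(
    "<mazur_fit> k = %.4g /s (a = %g pellets, n = %d points, SSE = %.4g)\n",
    x$k, x$a, x$n, x$sse
  ))
  invisible(x)
}

#' @export
predict.mazur_fit <- function(object, delay_s, ...) {
  hyperbolic_value(delay_s, object$k, object$a)
}

#' Normalized area under the discounting curve
#'
#' Trapezoidal area under the indifference-point-versus-delay curve with
#' delays normalized by the maximum delay and indifference points by the
#' delayed amount `a`, so the result lies in \[0, 1\]: 1 means no
#' discounting, 0 means complete discounting.
#'
#' @inheritParams fit_mazur
#' @return Unitless AUC in \[0, 1\].
#' @examples
#' auc_discounting(tibble::tibble(delay_s = c(0, 16),
#'                                indifference_point = c(6, 3)))  # 0.75
#' @export
auc_discounting <- function(data, a = 6) {
  stopifnot(all(c("delay_s", "indifference_point") %in% names(data)))
  data <- dplyr::arrange(data, .data$delay_s)
  if (nrow(data) < 2) stop("at least 2 delays are required for the AUC.")
  x <- data$delay_s / max(data$delay_s)
  y <- data$indifference_point / a
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Extra-sum-of-squares F test comparing two discounting curves
#'
#' Tests whether a single hyperbolic curve (one shared `k`) describes both
#' conditions as well as separate curves do:
#' `F = ((SSE_pooled - SSE_sep) / (df_p - df_s)) / (SSE_sep / df_s)` with
#' `df_p = N - 1` and `df_s = N - 2` (one fitted parameter per curve, `a`
#' fixed). A perfect separate fit (`SSE_sep = 0`) with remaining pooled
#' error yields an infinite F, flagged in the result.
#'
#' @param data_a,data_b Data frames with `delay_s` and `indifference_point`
#'   for the two conditions; both must cover the same set of delays.
#' @inheritParams fit_mazur
#' @return A one-row tibble of class `ess_f`: `statistic`, `df1`, `df2`,
#'   `p_value`, `k_pooled`, `k_a`, `k_b`, `sse_pooled`, `sse_separate`,
#'   `infinite` (logical flag).
#' @export
compare_curves_ess_f <- function(data_a, data_b, a = 6, k_max = 100) {
  if (!setequal(unique(data_a$delay_s), unique(data_b$delay_s))) {
    stop("both conditions must share the same set of delays.")
  }
  fa <- fit_k_ls(data_a$delay_s, data_a$indifference_point, a, k_max)
  fb <- fit_k_ls(data_b$delay_s, data_b$indifference_point, a, k_max)
  pooled <- dplyr::bind_rows(
    data_a[c("delay_s", "indifference_point")],
    data_b[c("delay_s", "indifference_point")]
  )
  fp <- fit_k_ls(pooled$delay_s, pooled$indifference_point, a, k_max)

  n <- nrow(pooled)
  df_p <- n - 1L
  df_s <- n - 2L
  sse_sep <- fa$sse + fb$sse
  tol <- 1e-12 * max(1, fp$sse)
  if (sse_sep <= tol) {
    if (fp$sse - sse_sep <= tol) {
      f_stat <- 0
      p <- 1
      infinite <- FALSE
    } else {
      f_stat <- Inf
      p <- 0
      infinite <- TRUE
    }
  } else {
    f_stat <- ((fp$sse - sse_sep) / (df_p - df_s)) / (sse_sep / df_s)
    f_stat <- max(f_stat, 0)
    p <- stats::pf(f_stat, df_p - df_s, df_s, lower.tail = FALSE)
    infinite <- FALSE
  }
  out <- tibble::tibble(
    statistic = f_stat, df1 = df_p - df_s, df2 = df_s, p_value = p,
    k_pooled = fp$k, k_a = fa$k, k_b = fb$k,
    sse_pooled = fp$sse, sse_separate = sse_sep,
    infinite = infinite
  )
  class(out) <- c("ess_f", class(out))
  out
}

#' Label choice trials by lever and i-value level
#'
#' Choice trials are stratified into four types by lever (immediate vs
#' delay) and i-value level (low: i-value < 4; high: i-value > 3).
#'
#' @param trials A trial table.
#' @return `trials` filtered to choice trials, with a `choice_type` column
#'   in `IM-low`, `IM-high`, `DEL-low`, `DEL-high`.
#' @export
label_choice_types <- function(trials) {
  trials |>
    dplyr::filter(.data$kind == "choice") |>
    dplyr::mutate(
      choice_type = paste0(
        ifelse(.data$chosen_lever == "immediate", "IM", "DEL"),
        ifelse(.data$i_value < 4, "-low", "-high")
      )
    )
}

#' Consecutive-choice run lengths of one choice type, with gamma fit
#'
#' Within each session, choice trials are labeled by lever x i-value level
#' (see [label_choice_types()]) and scanned for maximal runs of identical
#' labels. The run lengths of the requested type are pooled across sessions,
#' summarized as an empirical probability density over lengths, and fitted
#' with a gamma distribution by maximum likelihood (method-of-moments
#' initialization; runs of length 1 included).
#'
#' @param trials A trial table (one or more sessions).
#' @param type One of `"IM-low"`, `"IM-high"`, `"DEL-low"`, `"DEL-high"`.
#' @return An object of class `choice_runs`: `type`, `run_lengths`, `pdf`
#'   (tibble of `length`, `density`), `gamma_shape`, `gamma_scale` (NA with
#'   a warning when fewer than 2 runs, or when the MLE is degenerate).
#' @export
consecutive_choice_pdf <- function(trials,
                                   type = c("IM-low", "IM-high", "DEL-low", "DEL-high")) {
  type <- match.arg(type)
  labeled <- label_choice_types(trials)
  lens <- labeled |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_map(function(d, key) {
      r <- rle(d$choice_type)
      r$lengths[r$values == type]
    }) |>
    unlist()
  lens <- as.integer(lens %||% integer(0))

  tb <- table(lens)
  pdf <- tibble::tibble(
    length = as.integer(names(tb)),
    density = as.numeric(tb) / max(1L, length(lens))
  )

  shape <- scale <- NA_real_
  if (length(lens) < 2) {
    warning("fewer than 2 runs of type ", type, "; gamma fit skipped.")
  } else if (stats::var(lens) == 0) {
    warning("all runs of type ", type, " have equal length; gamma fit skipped.")
  } else {
    m <- mean(lens)
    v <- stats::var(lens)
    fit <- try(
      suppressWarnings(MASS::fitdistr(
        lens, "gamma",
        start = list(shape = m^2 / v, rate = m / v),
        lower = c(1e-6, 1e-6)
      )),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      warning("gamma MLE did not converge for type ", type, ".")
    } else {
      shape <- unname(fit$estimate["shape"])
      scale <- 1 / unname(fit$estimate["rate"])
    }
  }
  structure(
    list(
      type = type, run_lengths = lens, pdf = pdf,
      gamma_shape = shape, gamma_scale = scale
    ),
    class = "choice_runs"
  )
}

#' @export
print.choice_runs <- function(x, ...) {
  cat(sprintf(
    "<choice_runs> %s: %d runs, mean length %.2f, gamma(shape %.3g, scale %.3g)\n",
    x$type, length(x$run_lengths),
    if (length(x$run_lengths)) mean(x$run_lengths) else NA_real_,
    x$gamma_shape, x$gamma_scale
  ))
  invisible(x)
}

#' Rank-transformed latency contrast between trials 3 and 4 of runs
#'
#' Choice latencies are positively skewed, so paired third- and fourth-trial
#' latencies are transformed to ranks over the pooled set before averaging.
#' The paired comparison uses the Wilcoxon signed-rank test (exact null
#' distribution for n < 25 when there are no ties or zero differences,
#' normal approximation otherwise); the standardized statistic Z is also
#' reported.
#'
#' @param trial3,trial4 Paired numeric vectors of choice latencies (s) for
#'   the third and fourth trial of each run; `n >= 5` pairs required.
#' @return A one-row tibble: `n`, `mean_rank_trial3`, `mean_rank_trial4`,
#'   `V` (signed-rank statistic), `z`, `p_value`. With all differences zero,
#'   `z = 0` and `p_value = 1`.
#' @export
latency_rank_contrast <- function(trial3, trial4) {
  stopifnot(length(trial3) == length(trial4))
  n <- length(trial3)
  if (n < 5) stop("at least 5 pairs are required.")
  pooled_ranks <- rank(c(trial3, trial4))
  mr3 <- mean(pooled_ranks[seq_len(n)])
  mr4 <- mean(pooled_ranks[n + seq_len(n)])

  d <- trial4 - trial3
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(
      n = n, mean_rank_trial3 = mr3, mean_rank_trial4 = mr4,
      V = 0, z = 0, p_value = 1
    ))
  }
  r <- rank(abs(nz))
  v_plus <- sum(r[nz > 0])
  m <- length(nz)
  mu <- m * (m + 1) / 4
  tie_tab <- table(r)
  sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sig2 > 0) (v_plus - mu) / sqrt(sig2) else 0

  exact <- m < 25 && !any(duplicated(abs(nz))) && all(d != 0)
  p <- suppressWarnings(
    stats::wilcox.test(trial4, trial3, paired = TRUE, exact = exact)$p.value
  )
  tibble::tibble(
    n = n, mean_rank_trial3 = mr3, mean_rank_trial4 = mr4,
    V = v_plus, z = z, p_value = p
  )
}

#' Magnitude-discrimination criterion in pellets
#'
#' The zero-delay magnitude-discrimination criterion expressed in pellets:
#' a stated fraction of the maximum (delayed) reward value. An 80% criterion
#' of 6 pellets is 4.8; a 70% criterion is 4.2.
#'
#' @param criterion Fraction of the maximum reward value, in (0, 1\].
#' @param a Maximum reward value in pellets.
#' @return Criterion in pellets.
#' @export
magnitude_criterion <- function(criterion, a = 6) {
  stopifnot(is.numeric(criterion), criterion > 0, criterion <= 1)
  criterion * a
}

#' Neuron retention bookkeeping
#'
#' Summarizes ensemble-inclusion bookkeeping: of `starting` recorded
#' neurons, `excluded` failed the firing criterion (no spikes in the third
#' and fourth trials of every run type) and the remainder enter the
#' population analysis.
#'
#' @param starting Integer vector of starting neuron counts.
#' @param excluded Integer vector of excluded neuron counts.
#' @param label Optional labels (e.g. delay condition) for each row.
#' @return A tibble with `starting`, `excluded`, `retained`.
#' @export
retention_table <- function(starting, excluded, label = NULL) {
  stopifnot(length(starting) == length(excluded), all(excluded <= starting),
            all(excluded >= 0))
  out <- tibble::tibble(
    starting = as.integer(starting),
    excluded = as.integer(excluded),
    retained = as.integer(starting - excluded)
  )
  if (!is.null(label)) out <- dplyr::bind_cols(tibble::tibble(label = label), out)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
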