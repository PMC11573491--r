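#' Benjamini--Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence
#' among tests (the correction applied to per-timepoint t tests here).
#' Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @return Adjusted p values, same length; always `>=` the raw values.
#' @export
fdr_by <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = "BY")
}

#' One-way repeated-measures ANOVA with Greenhouse--Geisser correction
#'
#' Classical univariate repeated-measures F test for a single within-subject
#' factor, with degrees of freedom multiplied by the Greenhouse--Geisser
#' epsilon estimated from the double-centered covariance matrix of the
#' subject x level table:
#' `epsilon = tr(S)^2 / ((k - 1) * sum(S^2))`. With two levels epsilon is
#' exactly 1 and the F statistic equals the squared paired t statistic.
#'
#' @param data Long data frame with one observation per subject x level.
#' @param dv,subject,within Column names (strings) of the response, the
#'   subject identifier and the within-subject factor.
#' @return A one-row tibble (`TestResult` layout): `method`, `statistic`,
#'   `df1`, `df2`, `epsilon`, `p_raw`, `p_adjusted` (the GG-corrected p),
#'   `correction`.
#' @export
rm_anova_gg <- function(data, dv, subject, within) {
  stopifnot(all(c(dv, subject, within) %in% names(data)))
  wide <- data |>
    dplyr::select(dplyr::all_of(c(subject, within, dv))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(dv))
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (any(is.na(m))) stop("missing cells: the design must be balanced.")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 factor levels.")

  grand <- mean(m)
  ss_factor <- n * sum((colMeans(m) - grand)^2)
  ss_subject <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_factor - ss_subject

  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_factor <- ss_factor / df1
  ms_error <- ss_error / df2

  s <- stats::cov(m)
  s_dc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  denom <- (k - 1) * sum(s_dc^2)
  eps <- if (denom > 0) sum(diag(s_dc))^2 / denom else 1
  eps <- min(max(eps, 1 / (k - 1)), 1)

  if (ms_error <= .Machine$double.eps * max(1, abs(ms_factor))) {
    f_stat <- if (ms_factor <= .Machine$double.eps) 0 else Inf
  } else {
    f_stat <- ms_factor / ms_error
  }
  p_raw <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  if (f_stat == 0) p_raw <- p_gg <- 1

  tibble::tibble(
    method = "rm_anova",
    statistic = f_stat,
    df1 = eps * df1, df2 = eps * df2,
    epsilon = eps,
    p_raw = p_raw,
    p_adjusted = p_gg,
    correction = "greenhouse-geisser"
  )
}
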