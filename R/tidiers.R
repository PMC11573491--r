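#' Tidy a hyperbolic discounting fit
#'
#' @param x A `mazur_fit`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @method tidy mazur_fit
#' @export
tidy.mazur_fit <- function(x, ...) {
  tibble::tibble(term = "k", estimate = x$k)
}

#' @rdname tidy.mazur_fit
#' @return `glance()`: one-row model summary (`k`, `a`, `sse`, `auc`, `n`).
#' @method glance mazur_fit
#' @export
glance.mazur_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, a = x$a, sse = x$sse,
    auc = auc_discounting(x$data, a = x$a),
    n = x$n
  )
}

#' Tidy a state space into its trajectory coordinates
#'
#' @param x A `state_space`.
#' @param ... Unused.
#' @return The scores tibble (`trial_type`, `bin`, `PC1..`).
#' @method tidy state_space
#' @export
tidy.state_space <- function(x, ...) {
  x$scores
}

#' @rdname tidy.state_space
#' @return `glance()`: one row with the variance explained by the leading
#'   components and the problem size.
#' @method glance state_space
#' @export
glance.state_space <- function(x, ...) {
  ev <- x$explained_variance
  k <- x$n_components
  tibble::tibble(
    n_neurons = nrow(x$loadings),
    n_rows = nrow(x$scores_matrix),
    n_components = k,
    var_explained_top = sum(ev[seq_len(k)]),
    var_explained_pc1 = ev[1]
  )
}

#' Tidy per-session distance results
#'
#' @param x A `session_distances`.
#' @param ... Unused.
#' @return Long tibble of per-bin distances per run type.
#' @method tidy session_distances
#' @export
tidy.session_distances <- function(x, ...) {
  x$distances
}

#' @rdname tidy.session_distances
#' @method glance session_distances
#' @export
glance.session_distances <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "run_type",
                     values_from = "mean_distance")
}

#' Tidy condition averages and their per-bin tests
#'
#' @param x A `condition_averages`.
#' @param ... Unused.
#' @return The per-condition average traces.
#' @method tidy condition_averages
#' @export
tidy.condition_averages <- function(x, ...) {
  x$averages
}
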