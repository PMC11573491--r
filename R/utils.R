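#' @importFrom rlang .data
#' @importFrom stats predict
NULL

# Evaluate `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; run as-is when seed is NULL.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Population (ddof = 0) or sample (ddof = 1) standard deviation.
sd_ddof <- function(x, ddof = 0) {
  n <- length(x)
  if (n <= ddof) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / (n - ddof))
}

#' @export
generics::tidy

#' @export
generics::glance
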