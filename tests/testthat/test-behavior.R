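make_session <- function(i_values, kinds = rep("choice", length(i_values))) {
  tibble::tibble(
    session_id = "s1", delay_s = 8, laser = "off",
    trial_index = seq_along(i_values),
    kind = kinds,
    chosen_lever = "delay",
    i_value = i_values
  )
}

test_that("indifference point averages the last 10 choice trials, forced excluded", {
  expect_equal(indifference_point(make_session(rep(3L, 12))), 3)

  mix <- c(0L, 6L, 5L, 4L, 4L, 5L, 6L, 3L, 4L, 5L) # sums to 42
  expect_equal(indifference_point(make_session(c(2L, 2L, mix))), 4.2)

  # interleaved forced trials with extreme i-values are ignored
  iv <- c(rep(3L, 10), rep(0L, 5))
  kinds <- c(rep("choice", 10), rep("forced", 5))
  expect_equal(indifference_point(make_session(iv, kinds)), 3)

  expect_error(indifference_point(make_session(rep(3L, 9))), "choice trials")
})

test_that("indifference_points returns one row per session", {
  s <- dplyr::bind_rows(
    make_session(rep(2L, 10)),
    make_session(rep(4L, 10)) |> dplyr::mutate(session_id = "s2", delay_s = 4)
  )
  ips <- indifference_points(s)
  expect_equal(nrow(ips), 2)
  expect_setequal(ips$indifference_point, c(2, 4))
})

test_that("hyperbolic fit recovers exact parameters and handles no discounting", {
  d <- c(0, 1, 2, 4, 8, 16)
  exact <- tibble::tibble(delay_s = d, indifference_point = 6 / (1 + 0.5 * d))
  fit <- fit_mazur(exact)
  expect_equal(fit$k, 0.5, tolerance = 1e-5)
  expect_lt(fit$sse, 1e-8)
  expect_equal(hyperbolic_value(2, 0.5), 3)

  flat <- tibble::tibble(delay_s = d, indifference_point = 6)
  expect_equal(fit_mazur(flat)$k, 0)

  expect_error(fit_mazur(tibble::tibble(delay_s = c(4, 4), indifference_point = c(3, 3))),
               "distinct delays")
})

test_that("noisy discount-rate fit agrees with a fine grid-search oracle", {
  set.seed(21)
  d <- c(0, 1, 2, 4, 8, 16)
  for (rep in 1:10) {
    ip <- pmin(6, pmax(0, 6 / (1 + 0.25 * d) + rnorm(6, 0, 0.2)))
    dat <- tibble::tibble(delay_s = d, indifference_point = ip)
    fit <- fit_mazur(dat)
    grid <- seq(0, 2, by = 1e-4)
    sse <- vapply(grid, function(k) sum((ip - 6 / (1 + k * d))^2), numeric(1))
    k_oracle <- grid[which.min(sse)]
    expect_equal(fit$k, k_oracle, tolerance = 1e-3)
    expect_lte(fit$sse, min(sse) + 1e-8)
  }
})

test_that("fitted k converges to the true rate as noise shrinks", {
  d <- c(0, 1, 2, 4, 8, 16)
  med_err <- vapply(c(0.4, 0.1, 0.01), function(sg) {
    errs <- vapply(1:40, function(s) {
      set.seed(s)
      ip <- pmin(6, pmax(0, 6 / (1 + 0.25 * d) + rnorm(6, 0, sg)))
      abs(fit_mazur(tibble::tibble(delay_s = d, indifference_point = ip))$k - 0.25)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 0.005)
})

test_that("normalized AUC matches hand-computed trapezoids and is monotone", {
  d6 <- tibble::tibble(delay_s = c(0, 1, 2, 4, 8, 16), indifference_point = 6)
  expect_equal(auc_discounting(d6), 1)
  expect_equal(auc_discounting(dplyr::mutate(d6, indifference_point = 0)), 0)
  expect_equal(
    auc_discounting(tibble::tibble(delay_s = c(0, 16), indifference_point = c(6, 3))),
    0.75
  )
  # pointwise decrease cannot increase the AUC
  set.seed(3)
  for (rep in 1:20) {
    ip <- runif(6, 0, 6)
    base <- tibble::tibble(delay_s = c(0, 1, 2, 4, 8, 16), indifference_point = ip)
    lower <- dplyr::mutate(base, indifference_point = ip - runif(6, 0, ip))
    expect_lte(auc_discounting(lower), auc_discounting(base) + 1e-12)
  }
})

test_that("extra-sum-of-squares F test: identical conditions give F = 0, p = 1", {
  d <- c(0, 1, 2, 4, 8, 16)
  a <- tibble::tibble(delay_s = d, indifference_point = 6 / (1 + 0.3 * d) + c(.1, -.1, .2, 0, -.2, .1))
  out <- compare_curves_ess_f(a, a)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_false(out$infinite)
})

test_that("noiseless curves with different k give a flagged infinite F", {
  d <- c(0, 1, 2, 4, 8, 16)
  a <- tibble::tibble(delay_s = d, indifference_point = 6 / (1 + 0.1 * d))
  b <- tibble::tibble(delay_s = d, indifference_point = 6 / (1 + 1.0 * d))
  out <- compare_curves_ess_f(a, b)
  expect_true(out$infinite)
  expect_identical(out$statistic, Inf)
  expect_error(compare_curves_ess_f(a, dplyr::mutate(b, delay_s = delay_s + 1)),
               "share the same set of delays")
})

test_that("F test is calibrated under a shared-k null", {
  # quick calibration check; the full 1,000-rep version runs with the
  # acceptance suite
  d <- rep(c(0, 1, 2, 4, 8, 16), each = 4)
  set.seed(8)
  rej <- vapply(1:200, function(r) {
    ya <- 6 / (1 + 0.3 * d) + rnorm(length(d), 0, 0.3)
    yb <- 6 / (1 + 0.3 * d) + rnorm(length(d), 0, 0.3)
    compare_curves_ess_f(
      tibble::tibble(delay_s = d, indifference_point = ya),
      tibble::tibble(delay_s = d, indifference_point = yb)
    )$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("consecutive-choice runs are segmented by type and fully account for choice trials", {
  # IMlow, IMlow, IMlow, DELlow -> IM-low run lengths {3}
  tr <- tibble::tibble(
    session_id = "s1",
    trial_index = 1:4,
    kind = "choice",
    chosen_lever = c("immediate", "immediate", "immediate", "delay"),
    i_value = c(1L, 2L, 1L, 0L)
  )
  runs <- consecutive_choice_pdf(tr, "IM-low") |> suppressWarnings()
  expect_identical(runs$run_lengths, 3L)
  expect_equal(sum(runs$pdf$density), 1)

  # alternating levers: all run lengths 1
  alt <- tibble::tibble(
    session_id = "s1", trial_index = 1:8, kind = "choice",
    chosen_lever = rep(c("immediate", "delay"), 4),
    i_value = rep(2L, 8)
  )
  r_im <- suppressWarnings(consecutive_choice_pdf(alt, "IM-low"))
  r_del <- suppressWarnings(consecutive_choice_pdf(alt, "DEL-low"))
  expect_true(all(r_im$run_lengths == 1L))
  expect_true(all(r_del$run_lengths == 1L))

  # accounting invariant: run lengths across the four types partition choice trials
  set.seed(14)
  tr2 <- tibble::tibble(
    session_id = rep(c("a", "b"), each = 40),
    trial_index = rep(1:40, 2),
    kind = sample(c("choice", "forced"), 80, TRUE, c(.8, .2)),
    chosen_lever = sample(c("immediate", "delay"), 80, TRUE),
    i_value = sample(0:6, 80, TRUE)
  )
  total <- sum(vapply(
    c("IM-low", "IM-high", "DEL-low", "DEL-high"),
    function(ty) sum(suppressWarnings(consecutive_choice_pdf(tr2, ty))$run_lengths),
    numeric(1)
  ))
  expect_equal(total, sum(tr2$kind == "choice"))
})

test_that("gamma fit by MLE recovers run-length distribution parameters approximately", {
  set.seed(9)
  lens <- pmax(1L, as.integer(round(rgamma(400, shape = 3, scale = 1.2))))
  # build a lever sequence realizing exactly these IM-low run lengths
  levers <- unlist(lapply(lens, function(L) c(rep("immediate", L), "delay")))
  tr <- tibble::tibble(
    session_id = "s1", trial_index = seq_along(levers), kind = "choice",
    chosen_lever = levers, i_value = 1L
  )
  out <- consecutive_choice_pdf(tr, "IM-low")
  expect_identical(sort(out$run_lengths), sort(as.integer(lens)))
  expect_gt(out$gamma_shape, 1.5)
  expect_lt(abs(out$gamma_shape * out$gamma_scale - mean(lens)), 0.5)
  # fewer than 2 runs: warn, skip fit
  expect_warning(
    consecutive_choice_pdf(tr[1:3, ], "DEL-low"),
    "fewer than 2 runs"
  )
})

test_that("two samples from one gamma give uniform-looking KS p values", {
  set.seed(31)
  ps <- vapply(1:120, function(r) {
    x <- rgamma(50, 3, 1)
    y <- rgamma(50, 3, 1)
    suppressWarnings(stats::ks.test(x, y)$p.value)
  }, numeric(1))
  # roughly uniform: no excess of small p values, central mass in place
  expect_lt(mean(ps < 0.05), 0.1)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.7)
})

test_that("latency rank contrast handles identical, shifted and degenerate pairs", {
  x <- c(1.2, 0.8, 1.5, 2.0, 0.9, 1.1)
  same <- latency_rank_contrast(x, x)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_rank_trial3, same$mean_rank_trial4)

  up <- latency_rank_contrast(x, x + 0.5)
  expect_equal(up$V, length(x) * (length(x) + 1) / 2) # maximal signed-rank statistic
  expect_gt(up$mean_rank_trial4, up$mean_rank_trial3)
  expect_lt(up$p_value, 0.05)

  expect_error(latency_rank_contrast(x[1:3], x[1:3]), "at least 5 pairs")
})

test_that("signed-rank p matches the exhaustive sign-flip oracle for untied pairs", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 10
    t3 <- rlnorm(n)
    t4 <- t3 * rlnorm(n, 0.2, 0.3)
    got <- latency_rank_contrast(t3, t4)

    d <- t4 - t3
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    v_obs <- sum(r[d > 0])
    p_oracle <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
    expect_equal(got$p_value, p_oracle, tolerance = 1e-10)
  }
})

test_that("magnitude criteria and retention bookkeeping are exact", {
  expect_equal(magnitude_criterion(0.8), 4.8)
  expect_equal(magnitude_criterion(0.7), 4.2)
  expect_error(magnitude_criterion(1.2))
  tab <- retention_table(c(2120, 2078), c(1539, 912))
  expect_identical(tab$retained, c(581L, 1166L))
  expect_error(retention_table(10, 11))
})
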