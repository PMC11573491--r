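test_that("bin counts follow the inclusive-endpoint convention", {
  expect_identical(bin_count(c(-15, 15), 0.2), 151L)
  expect_identical(bin_count(c(-19, 1), 0.2), 101L)
  expect_identical(bin_count(c(0, 1), 1), 2L)
  expect_error(bin_count(c(0, 1), 0), "positive")
  expect_error(bin_count(c(1, 0), 0.2), "end must exceed")
  expect_equal(bin_centers(c(0, 1), 1), c(0, 1))
})

test_that("alignment puts spikes in the right bins and converts to rates", {
  sp <- tibble::tibble(neuron_id = 1L, spike_time = 100)
  tens <- align_and_bin(sp, events = 100, window = c(-1, 1), bin_width = 0.2)
  expect_equal(dim(tens), c(1, 11, 1))
  center <- which(abs(attr(tens, "time")) < 1e-9)
  expect_equal(unname(tens[1, center, 1]), 1 / 0.2)
  expect_equal(sum(tens), 1 / 0.2)

  # empty spike train: all-zero tensor for the declared neuron set
  empty <- tibble::tibble(neuron_id = integer(0), spike_time = numeric(0))
  z <- align_and_bin(empty, events = 100, window = c(-1, 1), neuron_ids = 1:3)
  expect_true(all(z == 0))
  expect_equal(dim(z), c(3, 11, 1))

  expect_error(align_and_bin(sp, events = numeric(0)), "empty")
  # windows reaching before the recording start are flagged
  t2 <- align_and_bin(sp, events = c(5, 100), window = c(-19, 1))
  expect_identical(attr(t2, "truncated"), c(TRUE, FALSE))
})

test_that("mean binned rate of a Poisson train approaches its intensity", {
  set.seed(2)
  lambda <- 12
  dur <- 4000
  sp <- tibble::tibble(
    neuron_id = 1L,
    spike_time = sort(runif(rpois(1, lambda * dur), 0, dur))
  )
  tens <- align_and_bin(sp, events = dur / 2, window = c(-1900, 1900), bin_width = 1)
  expect_equal(mean(tens), lambda, tolerance = 0.02)
})

test_that("smoothing matches direct convolution and conserves structure", {
  # impulse -> boxcar of height 1/5
  imp <- matrix(0, 1, 21)
  imp[1, 11] <- 1
  sm <- smooth_rates(imp, "moving_average", span = 5)
  expect_equal(as.numeric(sm[1, 9:13]), rep(1 / 5, 5))
  expect_equal(sum(sm), 1) # total conserved away from edges

  # constant series unchanged under reflected padding
  const <- matrix(3, 2, 30)
  expect_equal(smooth_rates(const, "moving_average"), const)
  expect_equal(smooth_rates(const, "gaussian", sigma = 0.25), const)

  # random series vs direct convolution oracle
  set.seed(6)
  x <- matrix(rnorm(50), 1)
  for (span in c(3, 5)) {
    kern <- rep(1 / span, span)
    half <- (span - 1) / 2
    n <- ncol(x)
    padded <- c(x[1, (half + 1):2], x[1, ], x[1, (n - 1):(n - half)])
    want <- vapply(seq_len(n), function(t) sum(padded[t:(t + span - 1)] * kern), numeric(1))
    got <- smooth_rates(x, "moving_average", span = span)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }

  expect_error(smooth_rates(matrix(1, 1, 3), "moving_average", span = 5), "longer")
  expect_error(smooth_rates(matrix(1, 1, 10), "moving_average", span = 4), "odd")
})

test_that("binning and smoothing are linear before z-scoring", {
  set.seed(12)
  spA <- tibble::tibble(neuron_id = rep(1:2, each = 30),
                        spike_time = runif(60, 0, 60))
  spB <- tibble::tibble(neuron_id = rep(1:2, each = 40),
                        spike_time = runif(80, 0, 60))
  ev <- 30
  w <- c(-19, 1)
  tA <- smooth_rates(align_and_bin(spA, ev, w, neuron_ids = 1:2))
  tB <- smooth_rates(align_and_bin(spB, ev, w, neuron_ids = 1:2))
  tAB <- smooth_rates(align_and_bin(dplyr::bind_rows(spA, spB), ev, w, neuron_ids = 1:2))
  expect_equal(as.numeric(tAB), as.numeric(tA) + as.numeric(tB), tolerance = 1e-12)
})

test_that("z-scoring standardizes each neuron and drops flat ones", {
  m <- matrix(c(1, 2, 3), 1)
  z <- zscore_rates(m)
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  set.seed(7)
  m2 <- matrix(rnorm(5 * 40, mean = 3, sd = 2), 5)
  z2 <- zscore_rates(m2)
  expect_equal(rowMeans(z2), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z2, 1, function(v) sqrt(mean((v - mean(v))^2))),
               rep(1, 5), tolerance = 1e-12)
  # sample-sd variant is configurable
  z2s <- zscore_rates(m2, ddof = 1)
  expect_equal(apply(z2s, 1, sd), rep(1, 5), tolerance = 1e-12)

  m3 <- rbind(m2, 7) # constant neuron
  expect_message(z3 <- zscore_rates(m3), "zero-variance")
  expect_equal(nrow(z3), 5)

  arr <- array(rnorm(3 * 10 * 4, 5), c(3, 10, 4))
  tz <- zscore_rates(make_tensor(arr, window = c(-0.9, 0.9)))
  flat <- matrix(tz, nrow = 3)
  expect_equal(rowMeans(flat), rep(0, 3), tolerance = 1e-12)
})

test_that("condition averages flag exactly the bins carrying an injected offset", {
  set.seed(42)
  nn <- 50; nb <- 151; per <- 6
  labels <- rep(c("IM-low", "IM-high", "DEL-low", "DEL-high"), each = per)
  arr <- array(rnorm(nn * nb * length(labels), 0, 0.1), c(nn, nb, length(labels)))
  hot <- 80:100
  arr[, hot, labels == "IM-high"] <- arr[, hot, labels == "IM-high"] + 1
  ca <- condition_averages(make_tensor(arr), labels)

  im <- dplyr::filter(ca$tests, contrast == "IM-low vs IM-high")
  expect_setequal(im$bin[im$significant], hot)
  del <- dplyr::filter(ca$tests, contrast == "DEL-low vs DEL-high")
  expect_false(any(del$significant))

  # adjusted p never falls below raw p (Benjamini-Yekutieli property)
  expect_true(all(ca$tests$p_adjusted >= ca$tests$p_raw - 1e-15))

  # identical conditions: nothing significant
  arr0 <- array(rnorm(10 * 51 * 8, 0, 1), c(10, 51, 8))
  ca0 <- condition_averages(make_tensor(arr0), rep(c("IM-low", "IM-high", "DEL-low", "DEL-high"), 2))
  expect_false(any(ca0$tests$significant))

  expect_error(
    condition_averages(make_tensor(arr0), rep(c("IM-low", "IM-high", "DEL-low", "DEL-low"), 2)),
    "at least 2 trials"
  )
})

test_that("the firing criterion retains only neurons active in every run category", {
  ev <- synth_run_events(n_per_type = 1)
  # neuron 1 fires near every event; neuron 2 misses the DEL-FtC trial-4 window
  skip_ev <- ev$run_type == "DEL-FtC" & ev$position == 4L
  sp <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, spike_time = ev$t_choice - 1),
    tibble::tibble(neuron_id = 2L, spike_time = ev$t_choice[!skip_ev] - 1)
  )
  filt <- filter_firing_neurons(sp, ev)
  expect_identical(filt$neuron_ids, 1L)
  expect_identical(filt$summary$starting, 2L)
  expect_identical(filt$summary$excluded, 1L)
  expect_identical(filt$summary$retained, 1L)
  expect_false(filt$by_category["2", "DEL-FtC-T4"])
})

test_that("aligned tensors round-trip through CSV + JSON persistence", {
  set.seed(5)
  sp <- tibble::tibble(neuron_id = rep(1:3, each = 20), spike_time = runif(60, 0, 50))
  tens <- align_and_bin(sp, events = c(20, 30), window = c(-5, 5))
  path <- file.path(tempdir(), "tensor_roundtrip")
  write_aligned_tensor(tens, path)
  back <- read_aligned_tensor(path)
  expect_equal(as.numeric(back), as.numeric(tens))
  expect_equal(attr(back, "window"), attr(tens, "window"))
  expect_equal(attr(back, "truncated"), attr(tens, "truncated"))
})
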