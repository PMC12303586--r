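test_that("population distance is Euclidean and satisfies the metric axioms", {
  a <- c(3, 4, rep(0, 98))
  expect_equal(population_distance(a, numeric(100)), 5)
  expect_equal(population_distance(a, a), 0)
  expect_error(population_distance(1:3, 1:4), "dimension")
  set.seed(1)
  for (i in 1:25) {
    x <- runif(20, 0, 50); y <- runif(20, 0, 50); z <- runif(20, 0, 50)
    expect_gte(population_distance(x, y), 0)
    expect_equal(population_distance(x, y), population_distance(y, x))
    expect_lte(population_distance(x, z),
               population_distance(x, y) + population_distance(y, z) + 1e-12)
  }
})

test_that("spectral estimation recovers synthetic sinusoids to within one bin", {
  t <- seq(0, 4999)
  x <- 3 * sin(2 * pi * 8 * t / 1000) + 1 * sin(2 * pi * 20 * t / 1000)
  ps <- lfp_spectrum(x, dt = 1, segment_ms = 500)
  expect_equal(spectrum_peak(ps), 8)
  expect_equal(ps$power[ps$freq == 8], 1)
  # the weaker 20 Hz component appears as the in-band local maximum
  expect_equal(band_local_max(ps, 12, 30), 20)
  pure <- lfp_spectrum(sin(2 * pi * 8 * t / 1000), dt = 1, segment_ms = 500)
  expect_equal(spectrum_peak(pure), 8)
  expect_error(lfp_spectrum(x[1:200]), "500 ms")
})

test_that("total spectral power tracks the trace variance (Parseval)", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.8), 2048)) + sin(2 * pi * 8 * (1:2048) / 1000)
  ps <- lfp_spectrum(x, dt = 1, segment_ms = 2048, window = "rect")
  total <- sum(ps$raw) * ps$df
  expect_equal(total, mean((x - mean(x))^2), tolerance = 0.01)
})

test_that("band power averages normalized power over 12-30 Hz", {
  t <- seq_len(4000) - 1
  x <- sin(2 * pi * 8 * t / 1000)
  ps <- lfp_spectrum(x, dt = 1, segment_ms = 500)
  expect_lt(band_power(ps, 12, 30), 0.05)
  expect_error(band_power(ps, 600, 700), "no frequency bins")
})

test_that("the adaptation curve is reciprocal ISI indexed by interval number", {
  st <- list(c(0, 10, 30, 70))  # ISIs 10, 20, 40 ms
  cv <- adaptation_curve(st, n_intervals = 3)
  expect_equal(cv$frequency, c(100, 50, 25))
  expect_equal(cv$interval, 1:3)
  flat <- adaptation_curve(list(seq(0, 900, by = 100)), n_intervals = 8)
  expect_true(all(flat$frequency == 10))
  # too few spikes: flagged and excluded
  few <- adaptation_curve(list(c(0, 10), seq(0, 100, by = 10)), n_intervals = 8)
  expect_equal(attr(few, "excluded"), 1L)
  expect_equal(unique(few$cell), 2L)
})

test_that("sustained drive produces declining instantaneous rates in pyramidal cells", {
  ex <- pyr_adaptation_experiment(n_cells = 10, seed = 21)
  expect_equal(length(unique(ex$curve$cell)), 10)
  expect_lt(ex$correlation$estimate, -0.4)
  expect_lt(ex$correlation$p.value, 0.01)
  # expected instantaneous frequency does not increase across the first 8 APs
  med <- tapply(ex$curve$frequency, ex$curve$interval, mean)
  expect_lt(med[8], med[1])
  expect_lt(mean(diff(med) > 0), 0.5)
})

test_that("rheobase curves are monotone in input and in OXT level", {
  rb <- rheobase_curve(c(0, 3.5, 5), n_repeats = 12, duration = 100, seed = 3)
  z <- rb[rb$amplitude == 0, ]
  expect_true(all(z$p_spike == 0))
  for (lv in c("low", "medium", "high")) {
    p <- rb$p_spike[rb$oxt_level == lv]
    expect_true(all(diff(p) >= 0))
  }
  mid <- rb[rb$amplitude == 3.5, ]
  expect_gte(mid$p_spike[mid$oxt_level == "high"],
             mid$p_spike[mid$oxt_level == "medium"])
  expect_gte(mid$p_spike[mid$oxt_level == "medium"],
             mid$p_spike[mid$oxt_level == "low"])
})

test_that("accumulation curves are non-decreasing running totals", {
  empty <- accumulate_spikes(data.frame(t = numeric(0), pop = character(0),
                                        id = integer(0)), grid_ms = 100)
  expect_true(all(empty$count == 0) || nrow(empty) == 0)
  sp <- data.frame(t = c(50, 150, 950, 2500), pop = "Pyr", id = 1L)
  ac <- accumulate_spikes(sp, grid_ms = 1000)
  expect_equal(ac$count, c(3, 3))
  expect_true(all(diff(ac$count) >= 0))
})

test_that("paired rate test matches t.test and flags degenerate inputs", {
  pre <- c(4.2, 5.1, 3.8, 6.0, 5.5)
  post <- pre + c(1.2, 0.8, 1.5, 0.9, 1.1)
  res <- paired_rate_test(pre, post)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_true(res$significant)
  same <- paired_rate_test(pre, pre)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  shift <- paired_rate_test(pre, pre + 1)
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p_value))
  expect_error(paired_rate_test(1:3, 1:4), "paired")
  expect_error(paired_rate_test(1, 2), "two pairs")
})
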