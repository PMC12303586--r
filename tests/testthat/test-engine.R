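test_that("an undriven network stays silent at rest with a flat LFP", {
  cfg <- tiny_config(osn_baseline = 0)
  net <- build_network(cfg, seed = 1)
  set.seed(1)
  rec <- run_simulation(net, blank_odor(30), sim_settings(duration = 500))
  expect_equal(nrow(rec$spikes), 0)
  expect_equal(length(rec$lfp), 500)
  expect_true(all(rec$lfp == -65))
})

test_that("membrane response with silent synapses matches the closed-form linear ODE", {
  # single-cell reduction under constant subthreshold drive: the Euler
  # solution is v_rest + D (1 - (1 - dt/tau)^k)
  sim <- aonsim:::simulate_pyr_cells(3, drive_mv = 2, duration = 100,
                                     jitter_fraction = 0, seed = 1)
  k <- seq_len(100)
  expect_equal(sim$v[, 1], -65 + 2 * (1 - 0.9^k), tolerance = 1e-10)
  expect_equal(length(sim$spike_times[[1]]), 0)  # 2 mV is below rheobase
})

test_that("plasticity with zero learning rate leaves the weights untouched", {
  net <- build_network(aon_config(), seed = 7)
  w0 <- net$synapses$Pyr_Pyr$W
  od <- make_odor_pair(seed = 7)$familiar
  set.seed(7)
  rec <- run_simulation(net, od, sim_settings(duration = 1000,
                                              plasticity = TRUE, alpha = 0))
  expect_identical(rec$network$synapses$Pyr_Pyr$W, w0)
  # non-plastic classes never change regardless
  expect_identical(rec$network$synapses$MC_Pyr$W, net$synapses$MC_Pyr$W)
})

test_that("hebbian update implements the spike-count product rule with a cap", {
  W <- matrix(c(0, 1e-4, 1e-4, 0), 2, 2)
  mask <- (W > 0) * 1
  cnt <- c(4, 5)
  W2 <- hebbian_update(W, cnt, 0.001, 1, mask)
  expect_equal(W2[1, 2], 1e-4 + 0.001 * 4 * 5)   # Delta w = alpha x_i x_j
  expect_equal(W2[2, 1], 1e-4 + 0.001 * 5 * 4)
  expect_equal(diag(W2), c(0, 0))                # non-connections stay zero
  expect_equal(hebbian_update(W, c(0, 0), 0.001, 1, mask), W)
  W3 <- W
  for (i in 1:50) W3 <- hebbian_update(W3, cnt, 0.01, 0.02, mask)
  expect_true(all(W3 <= 0.02))
  expect_error(hebbian_update(W, cnt, -1, 1, mask), "non-negative")
})

test_that("weight change over a run equals the Hebbian rule recomputed from the raster", {
  net <- build_network(aon_config(), seed = 9)
  w0 <- net$synapses$Pyr_Pyr$W
  mask <- net$synapses$Pyr_Pyr$mask
  od <- make_odor_pair(seed = 9)$familiar
  set.seed(9)
  st <- settle(net)
  rec <- run_simulation(net, od, sim_settings(duration = 2000,
                                              plasticity = TRUE), st)
  # independent recomputation: per-cycle spike counts from the logged raster
  pyr <- rec$spikes[rec$spikes$pop == "Pyr", ]
  bounds <- c(rec$t_start, rec$sniff_boundaries)
  W <- w0
  for (b in seq_len(length(bounds) - 1)) {
    sel <- pyr$t >= bounds[b] & pyr$t < bounds[b + 1]
    cnt <- tabulate(pyr$id[sel], nbins = 100)
    W <- hebbian_update(W, cnt, 3.5e-4, 0.0075, mask)
  }
  expect_equal(rec$network$synapses$Pyr_Pyr$W, W, tolerance = 1e-12)
  # and the engine's own cycle log agrees with the raster
  expect_equal(nrow(rec$cycle_counts), length(rec$sniff_boundaries))
})

test_that("weight snapshots are elementwise non-decreasing during potentiation", {
  net <- build_network(aon_config(), seed = 10)
  od <- make_odor_pair(seed = 10)$familiar
  set.seed(10)
  st <- settle(net)
  rec <- run_simulation(net, od,
                        sim_settings(duration = 1000, plasticity = TRUE,
                                     record_weights = TRUE), st)
  snaps <- rec$weight_snapshots
  expect_gte(length(snaps), 7)
  for (i in seq_len(length(snaps) - 1))
    expect_true(all(snaps[[i + 1]] >= snaps[[i]]))
})

test_that("identical seeds give bit-identical records and distinct seeds differ", {
  net <- build_network(aon_config(), seed = 12)
  od <- make_odor_pair(seed = 12)$familiar
  set.seed(99)
  a <- run_simulation(net, od, sim_settings(duration = 300))
  set.seed(99)
  b <- run_simulation(net, od, sim_settings(duration = 300))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp, b$lfp)
  set.seed(100)
  c <- run_simulation(net, od, sim_settings(duration = 300))
  expect_false(identical(a$spikes, c$spikes))
})

test_that("phases share state: time, respiration phase and weights carry over", {
  net <- build_network(aon_config(), seed = 13)
  od <- make_odor_pair(seed = 13)$familiar
  set.seed(13)
  out <- run_phases(net, list(
    list(odor = blank_odor(), duration = 250, label = "settle"),
    list(odor = od, duration = 500, label = "test")))
  expect_equal(out$records$test$t_start, 250)
  expect_equal(out$records$test$sniff_boundaries,
               seq(375, 750, by = 125))
  expect_equal(out$records$test$state$t, 750)
})

test_that("run_repeats gives independent instantiations and flags duplicate seeds", {
  res <- run_repeats(c(1, 2), function(s) build_network(aon_config())$pops$Pyr$tau)
  expect_false(identical(res[[1]], res[[2]]))
  expect_warning(run_repeats(c(1, 1), function(s) 1), "duplicate")
  res2 <- run_repeats(1, function(s) build_network(aon_config())$pops$Pyr$tau)
  expect_identical(res[[1]], res2[[1]])
})

test_that("compute_lfp averages subthreshold voltages and rejects empty input", {
  v <- cbind(rep(-65, 10), -65 + sin(1:10))
  expect_equal(compute_lfp(v), -65 + sin(1:10) / 2)
  expect_error(compute_lfp(matrix(nrow = 5, ncol = 0)), "empty")
})

test_that("simulation records round-trip through the text exporters", {
  net <- build_network(tiny_config(jitter = 0.1), seed = 14)
  od <- odor_stimulus(c(rep(1, 7), rep(0, 23)), "familiar")
  set.seed(14)
  rec <- run_simulation(net, od, sim_settings(duration = 500))
  d <- withr::local_tempdir()
  write_sim_record(rec, d)
  back <- read_sim_record(d)
  expect_equal(nrow(back$spikes), nrow(rec$spikes))
  expect_equal(back$lfp, rec$lfp, tolerance = 1e-6)
  expect_equal(dim(back$weights), dim(rec$network$synapses$Pyr_Pyr$W))
})

test_that("settings validation rejects inconsistent requests", {
  expect_error(sim_settings(duration = 501.5), "multiple")
  expect_error(sim_settings(alpha = -1), "non-negative")
  expect_error(run_simulation(build_network(tiny_config(), seed = 1), "odor"),
               "odor_stimulus")
})
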