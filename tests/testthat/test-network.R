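test_that("default configuration carries the standard parameter-table values", {
  cfg <- aon_config()
  expect_equal(cfg$populations$Pyr$tau, 10)
  expect_equal(cfg$populations$Pyr$v_rest, -65)
  expect_equal(cfg$populations$Pyr$theta_min, -62)
  expect_equal(cfg$populations$Pyr$theta_max, -55)
  expect_equal(cfg$populations$MC$compartments, 2L)
  expect_equal(cfg$synapses$MC_Pyr$w_mean, 0.007)
  expect_equal(cfg$synapses$MC_Pyr$p, 0.20)
  expect_equal(cfg$synapses$MC_GC$p, 0.25)
  expect_equal(cfg$synapses$Pyr_Pyr$p, 0.15)
  expect_equal(cfg$synapses$Pyr_ET$p, 0.10)
  expect_equal(cfg$synapses$Pyr_GC$p, 0.20)
  # feedback to the bulb stays very weak
  expect_equal(cfg$synapses$Pyr_ET$w_mean, 0.0015)
  expect_equal(cfg$synapses$Pyr_GC$w_mean, 0.0015)
  # inhibition exactly where the circuit diagram puts it
  signs <- vapply(cfg$synapses, `[[`, "", "sign")
  expect_setequal(names(signs)[signs == "inhibitory"], c("PG_MC", "GC_MC"))
  expect_true(cfg$synapses$Pyr_Pyr$plastic)
  expect_equal(sum(vapply(cfg$synapses, `[[`, TRUE, "plastic")), 1L)
})

test_that("zero jitter reproduces the class means exactly", {
  net <- build_network(tiny_config(), seed = 1)
  expect_true(all(net$pops$Pyr$tau == 10))
  expect_true(all(net$pops$Pyr$theta_min == -62))
  w <- net$synapses$MC_Pyr$W
  expect_true(all(w[w > 0] == 0.007))
})

test_that("jittered parameters stay within 10 percent of their means", {
  taus <- unlist(lapply(1:10, function(s)
    build_network(aon_config(), seed = s)$pops$Pyr$tau))
  expect_gte(min(taus), 9)
  expect_lte(max(taus), 11)
  expect_lt(min(taus), 9.2)   # the draw actually spreads over the band
  expect_gt(max(taus), 10.8)
  net <- build_network(aon_config(), seed = 3)
  w <- net$synapses$MC_Pyr$W
  expect_gte(min(w[w > 0]), 0.007 * 0.9)
  expect_lte(max(w), 0.007 * 1.1)
  # thresholds remain ordered after jitter
  expect_true(all(net$pops$Pyr$theta_min < net$pops$Pyr$theta_max))
})

test_that("random projection counts follow the Bernoulli connectivity", {
  counts <- vapply(1:20, function(s) {
    net <- build_network(aon_config(), seed = s)
    sum(net$synapses$MC_Pyr$mask > 0)
  }, 0)
  # each realization within 3 binomial SDs of n^2 p = 2000
  sd3 <- 3 * sqrt(100 * 100 * 0.2 * 0.8)
  expect_true(all(abs(counts - 2000) < sd3 + 1))
  # and the batch mean much closer
  expect_lt(abs(mean(counts) - 2000), sd3 / 2)
})

test_that("column-aligned classes are wired deterministically", {
  net <- build_network(tiny_config(n = 25), seed = 2)
  # granule cells inhibit only their column's mitral cell
  gcmc <- net$synapses$GC_MC$mask
  expect_equal(sum(gcmc > 0), 25)
  expect_true(all(diag(gcmc) > 0))
  # one OSN per glomerular column
  expect_equal(sum(net$synapses$OSN_MC$mask > 0), 25)
  # no pyramidal self-connections
  expect_true(all(diag(net$synapses$Pyr_Pyr$mask) == 0))
  # ET surround couples each column to its two wrap-around neighbours
  expect_equal(sum(net$synapses$ET_ET$mask > 0), 50)
  expect_true(all(diag(net$synapses$ET_ET$mask) == 0))
})

test_that("a zero connection probability yields an empty class", {
  cfg <- tiny_config()
  cfg$synapses$Pyr_Pyr$p <- 0
  net <- build_network(cfg, seed = 1)
  expect_equal(sum(net$synapses$Pyr_Pyr$mask), 0)
})

test_that("the same seed reproduces the identical network", {
  a <- build_network(aon_config(), seed = 11)
  b <- build_network(aon_config(), seed = 11)
  expect_identical(a$synapses$MC_Pyr$W, b$synapses$MC_Pyr$W)
  expect_identical(a$pops$Pyr$theta_min, b$pops$Pyr$theta_min)
})

test_that("reversal conventions give excitatory and inhibitory driving forces from rest", {
  net <- build_network(tiny_config(), seed = 1)
  expect_equal(net$synapses$MC_Pyr$e_abs, 70)      # absolute, as printed
  expect_equal(net$synapses$PG_MC$e_abs, -70)      # -5 relative to -65 rest
  expect_equal(net$synapses$GC_MC$e_abs, -75)      # -10 relative to rest
  expect_gt(net$synapses$MC_Pyr$e_abs, -65)
  expect_lt(net$synapses$GC_MC$e_abs, -65)
})

test_that("connection sets and configurations round-trip through their text formats", {
  net <- build_network(tiny_config(n = 20, jitter = 0.1), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_connections(net, "MC_Pyr", f)
  df <- read_connections(f)
  expect_equal(nrow(df), sum(net$synapses$MC_Pyr$mask > 0))
  expect_equal(sort(df$weight), sort(net$synapses$MC_Pyr$W[net$synapses$MC_Pyr$mask > 0]))

  cfg <- aon_config(n = 40, respiration_hz = 6, osn_gain = 33)
  fc <- withr::local_tempfile(fileext = ".cfg")
  write_aon_config(cfg, fc)
  cfg2 <- read_aon_config(fc)
  expect_equal(cfg2$respiration_hz, 6)
  expect_equal(cfg2$osn_gain, 33)
  expect_equal(cfg2$populations$Pyr$n, 40)
  expect_equal(cfg2$synapses$MC_Pyr$w_mean, cfg$synapses$MC_Pyr$w_mean)
  expect_equal(cfg2$synapses$GC_MC$p, "local")
})
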