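test_that("conductance kernel is zero at onset, peak-normalized, and matches a brute-force grid", {
  expect_equal(conductance_kernel(0, 1, 2), 0)
  # dense grid search as independent oracle for the peak location and value
  tt <- seq(0, 20, by = 1e-3)
  g <- conductance_kernel(tt, 1, 2)
  expect_gte(min(g), 0)
  expect_equal(max(g), 1, tolerance = 1e-6)
  t_star <- tt[which.max(g)]
  expect_equal(t_star, (1 * 2 / (2 - 1)) * log(2 / 1), tolerance = 0.01)
  expect_equal(t_star, kernel_peak_time(1, 2), tolerance = 0.01)
  expect_equal(conductance_kernel(kernel_peak_time(1, 2), 1, 2), 1,
               tolerance = 1e-6)
  # decays toward zero
  expect_lt(conductance_kernel(50, 1, 2), 1e-6)
  expect_error(conductance_kernel(1, 2, 1), "rise time")
  expect_error(conductance_kernel(1, -1, 2), "positive")
})

test_that("firing probability is a piecewise-linear ramp between the thresholds", {
  expect_equal(firing_probability(-62, -62, -55), 0)
  expect_equal(firing_probability(-70, -62, -55), 0)
  expect_equal(firing_probability(-55, -62, -55), 1)
  expect_equal(firing_probability(-50, -62, -55), 1)
  expect_equal(firing_probability((-62 - 55) / 2, -62, -55), 0.5)
  expect_error(firing_probability(-60, -55, -62), "theta_min")
})

test_that("synaptic drive is conductance times driving force", {
  expect_equal(synaptic_drive(0.5, 1, -65, -65), 0)
  # mitral-to-pyramidal weight with unit conductance at rest
  expect_equal(synaptic_drive(0.007, 1, 5, -65), 0.49)
  expect_lt(synaptic_drive(0.0015, 1, -75, -63), 0)
})

test_that("Euler membrane update has the resting fixed point and the exact decay factor", {
  expect_equal(step_membrane(0, 0, 10, 1), 0)
  expect_equal(step_membrane(10, 0, 10, 1), 9)   # (1 - dt/tau) = 0.9
  # long-run convergence to the closed-form steady state of the linear ODE
  u <- 0
  for (k in 1:500) u <- step_membrane(u, 4.2, 10, 1)
  expect_equal(u, 4.2, tolerance = 1e-8)
  expect_error(step_membrane(0, 0, -1, 1), "positive")
})

test_that("adaptation calcium decays exponentially and is incremented by spikes", {
  spec <- adaptation_spec(ca_increment = 0.01)
  st <- update_adaptation(0, FALSE, spec, -65, 1)
  expect_equal(st$ca, 0)
  expect_equal(st$drive, 0)
  # one spike, then 100 ms of decay: ca = increment * exp(-1)
  ca <- update_adaptation(0, TRUE, spec, -65, 1)$ca
  for (k in 1:100) ca <- update_adaptation(ca, FALSE, spec, -65, 1)$ca
  expect_equal(ca, 0.01 * exp(-1), tolerance = 1e-12)
  # hyperpolarizing drive for v above the adaptation reversal
  expect_lt(update_adaptation(1, FALSE, spec, -60, 1)$drive, 0)
  expect_error(adaptation_spec(tau_ca = -1), "positive")
})

test_that("OXT lowers the output-function thresholds monotonically with a valid ramp", {
  pyr <- population_spec("Pyr", 100, 10, -65, -62, -55)
  lo <- apply_oxt_condition(pyr, "low")
  md <- apply_oxt_condition(pyr, "medium")
  hi <- apply_oxt_condition(pyr, "high")
  expect_equal(lo$theta_max, -55)
  expect_equal(md$theta_max, -60)
  expect_true(hi$theta_max < md$theta_max)
  for (s in list(lo, md, hi)) expect_lt(s$theta_min, s$theta_max)
  # thresholds stay above rest: no tonic firing at rest under any condition
  for (s in list(lo, md, hi)) expect_gt(s$theta_min, s$v_rest)
  # spike probability is pointwise non-decreasing in OXT level
  v <- seq(-66, -50, by = 0.1)
  p_lo <- firing_probability(v, lo$theta_min, lo$theta_max)
  p_md <- firing_probability(v, md$theta_min, md$theta_max)
  p_hi <- firing_probability(v, hi$theta_min, hi$theta_max)
  expect_true(all(p_md >= p_lo))
  expect_true(all(p_hi >= p_md))
  expect_error(apply_oxt_condition(pyr, "extreme"))
})
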