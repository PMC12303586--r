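# small network for fast engine tests: 30 cells per population, no jitter
# unless asked for
tiny_config <- function(n = 30, jitter = 0, ...) {
  aon_config(n = n, jitter_fraction = jitter, ...)
}

# a settled network state: run a short blank period so conductances and
# adaptation reach their working regime before measurements
settle <- function(network, ms = 250, settings = sim_settings()) {
  settings$duration <- ms
  run_simulation(network, blank_odor(network$pops$OSN$n), settings)$state
}
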