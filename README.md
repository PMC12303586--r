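# aonsim

Spiking-network simulation of social-odor learning in the anterior
olfactory nucleus (AON).

Recognition of a familiar conspecific's odor correlates with *enhanced* —
not habituated — responses in olfactory cortex, modulated by oxytocin
(OXT). `aonsim` implements the circuit model behind that account: a
probabilistic leaky integrate-and-fire network of the olfactory bulb
(sensory, periglomerular, external tufted, two-compartment mitral and
granule cells) feeding 100 AON pyramidal cells, with

- conductance synapses `w g(t) (E_N − v)` using peak-normalized
  difference-of-exponentials kernels,
- a linear-ramp Bernoulli spiking output `F(v)` between thresholds
  `θ_min` and `θ_max`,
- calcium-dependent spike-rate adaptation in pyramidal cells
  (`A_ahc · ca · (E_ahp − v)`, `τ_ca` = 100 ms),
- OXT modeled as a downward shift of the pyramidal thresholds (a rheobase
  decrease; low/medium/high conditions), and
- sniff-cycle Hebbian plasticity on the Pyr→Pyr synapses,
  `w_ij ← w_ij + α Σx_i Σx_j`, the spike-count product over the preceding
  sniff cycle, applied between cycles and clipped at a cap.

Odors are Gaussian activation profiles over 20–25% of the sensory neurons,
gated by an 8 Hz respiration envelope. Everything is simulated by forward
Euler at 1 ms with all parameters jittered ±10% per network instantiation.

The package reproduces, stochastically and at the original replicate
counts: the familiar-odor response enhancement after 5 s of learning under
medium/high OXT (and its absence under low OXT and for the novel odor),
growth of baseline-to-familiar population-vector distances, learned-odor
beta-band (12–30 Hz) LFP power, spike-rate adaptation and
rheobase-by-OXT curves, faster spike accumulation for the familiar odor,
and concentration series. See `vignette("aonsim-methods")` for the model
conventions, calibration rationale and known limitations.

## Worked example

```r
library(aonsim)
set.seed(101)
cfg   <- aon_config()               # populations, synapse classes, Table-style defaults
net   <- build_network(cfg)         # one jittered instantiation
odors <- make_odor_pair()           # familiar + novel odors
odors$familiar
#> odor_stimulus 'familiar': 25/100 OSNs active, peak 1, concentration 1

settle <- run_simulation(net, blank_odor(), sim_settings(duration = 250))
rec <- run_simulation(net, odors$familiar, sim_settings(duration = 5000),
                      settle$state)
rec
#> sim_record: odor 'familiar', 5000 ms from t = 250 ms, OXT medium
#>   spikes: OSN=87085 PG=12405 ET=19608 MC=8991 GC=0 Pyr=1561
#>   LFP: 5000 samples, mean -64.91 mV

summary(population_rates(rec))      # per-cell pyramidal rates, spikes/s
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.000   1.400   3.000   3.122   4.400   8.400

spec <- lfp_spectrum(rec$lfp)       # Welch estimate of the simulated LFP
spec
#> power_spectrum: 0-500 Hz, df = 2 Hz, 19 segment(s); peak at 8 Hz
band_power(spec)                    # mean normalized 12-30 Hz power
#> [1] 0.009072884
```

The spectrum peaks at the 8 Hz respiration (theta) frequency; pyramidal
responses are sparse and odor-selective before learning. Scripted
experiments — learning with pre/post tests across OXT levels, spectra,
distances, accumulation, concentration series — run via
`run_protocol(protocol_spec("fig3_learning"))` and friends, and a thin
command-line front end lives at `inst/cli/aonsim.R`.

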