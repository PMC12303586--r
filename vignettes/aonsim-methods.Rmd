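---
title: "Model and methods: odor learning in an olfactory bulb–AON spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: odor learning in an olfactory bulb-AON spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aonsim)
```

`aonsim` simulates a small olfactory circuit — sensory neurons (OSN),
periglomerular (PG), external tufted (ET), mitral (MC) and granule (GC) cells
of the olfactory bulb, plus 100 pyramidal cells (Pyr) of the anterior
olfactory nucleus (AON) — and asks what Hebbian plasticity among the AON
pyramidal cells does to odor representations. The headline phenomena it
reproduces are: enhanced pyramidal responses to a *familiar* (learned) odor
but not to a novel one, growth of the population-vector distance between the
familiar odor and baseline, the emergence of beta-band (12–30 Hz) power in
the simulated LFP specifically for the learned odor, and faster accumulation
of spikes for familiar than for novel input. Oxytocin (OXT) modulates all of
this by lowering pyramidal firing thresholds.

## Neurons and synapses

Every cell is a probabilistic leaky integrate-and-fire unit

$$\tau \frac{dv}{dt} + v(t) = V^{ext}(t),$$

integrated by forward Euler at `dt` = 1 ms, with `v` stored internally as a
deviation from the resting potential (−65 mV for every type) so that rest is
the zero fixed point. $V^{ext}$ sums sensory drive, synaptic drive and (for
pyramidal cells) the adaptation current. Each synapse class contributes
$w \, g(t) \, (E_N - v)$, with a difference-of-exponentials conductance

$$g(t) = \frac{e^{-t/\tau_2} - e^{-t/\tau_1}}{g_{peak}}, \qquad \tau_1 < \tau_2,$$

peak-normalized so that a single presynaptic spike drives a maximum
conductance of exactly 1 and all strength lives in the weight $w$. The
engine does not store spike histories: each class keeps two exponential
state variables per postsynaptic cell (one per time constant), decayed each
step and incremented by the summed weights of the presynaptic spikes, which
reproduces the superposition of kernels exactly in O(1) per step.

Spiking is probabilistic: the output function $F(v)$ is 0 below
$\theta^{min}$, 1 above $\theta^{max}$ and linear in between, and is read as
a per-millisecond Bernoulli spike probability. At most one spike per step is
possible; a spiking cell is reset to rest at the end of its step, giving an
implicit one-step refractory. Mitral cells have two compartments — an apical
compartment receiving OSN, PG and ET input, and a soma receiving GC input
and emitting spikes — coupled by a symmetric voltage-coupling term
(`mc_coupling`, default 0.8 per ms; values above ~0.9 are rejected because
the explicit Euler step becomes unstable). Only the soma is reset on a
spike.

**Reversal-potential convention.** Excitatory reversals are the printed
+70 mV, read as absolute potentials (a ~135 mV driving force from rest);
with those reversals reinterpreted relative to rest the driving force halves
and mitral cells cannot leave the near-threshold regime. The two inhibitory
reversals (−5 and −10 mV) are read as offsets from rest (−70 / −75 mV
absolute, GABA-A-like), since as absolute values they would be depolarizing.
Each synapse class carries a `relative_to_rest` flag, so either convention
can be selected per class. The adaptation reversal (−90 mV) is absolute, a
typical potassium reversal.

## Spike-rate adaptation

Pyramidal cells carry a calcium-like variable `ca` that jumps by
`ca_increment` at each spike and decays with $\tau_{ca} = 100$ ms; it gates
a hyperpolarizing current $A^{ahc} \, ca \, (E_{ahp} - v)$ with
$A^{ahc} = 10$ and $E_{ahp} = -90$ mV. Only the product
$A^{ahc} \cdot ca\_increment$ matters. The default increment (0.016) was
calibrated jointly against two constraints: the single-cell adaptation
profile (a declining instantaneous rate over the first eight action
potentials of a constant-drive response, with a pooled interval-number ×
rate correlation near −0.73; see `pyr_adaptation_experiment()`, default
drive 14 mV), and the network-level requirement that the
afterhyperpolarization bound recurrent excitation once the pyramidal network
has been potentiated. The second constraint is what makes the adaptation
this strong: with a weak AHP the potentiated network sits on a knife edge
between no effect and runaway population firing, whereas a strong AHP
terminates recurrent bursts, keeps the learning effect bounded and
comparable across network instantiations, and generates the post-learning
beta-band rhythmicity (burst–AHP–recovery cycles on the ~50 ms scale set by
the interplay of $\tau_{ca}$ with the burst size).

## Oxytocin

OXT raises pyramidal excitability by lowering the output-function
thresholds. Medium OXT uses the printed values (−62/−60 mV; low OXT is the
unmodulated −62/−55). The printed high-OXT saturation (−65 mV) lies below
both the resting potential and $\theta^{min}$, which would invert the ramp
or make cells fire tonically at rest; high OXT is therefore represented as
a fixed-width ramp 2 mV below the medium one (−64/−62). Spike probability
is pointwise non-decreasing in OXT level, and cells are silent at rest under
all three conditions. Learning phases run under the protocol's OXT level;
all test presentations use medium OXT.

## Network architecture

Each population has 100 cells in aligned "functional columns": OSN *i*
drives PG/ET/MC of column *i* only, each GC inhibits only its column's
mitral soma, and ET cells excite their ±1 neighbours (wrap-around;
`et_surround` flag). Random projections are Bernoulli per cell pair:
MC→GC (p = 0.25), MC→Pyr (0.2), Pyr→Pyr (0.15, no self-connections),
Pyr→ET (0.1) and Pyr→GC (0.2); the AON→bulb feedback weights are kept very
weak (0.0015) so feedback does not drive the phenomena. All membrane time
constants, synaptic weights and threshold *offsets from rest* are jittered
uniformly ±10% around their means per instantiation; jittering the absolute
threshold voltages instead would let $\theta^{min}$ cross $\theta^{max}$,
so the offsets are jittered and the resting potential is left fixed.

## Odors and respiration

An odor is a Gaussian amplitude profile across a contiguous block of OSN
columns covering 20–25% of the OSNs (maximal activation 1.0 at full
concentration), the profile-across-neurons reading of a "Gaussian
distribution of activities"; the familiar and novel odors share a small
fraction of their active sets (default 5%, realized as adjacent blocks with
the exact shared column count). Concentration scales the activation vector
multiplicatively. OSN drive is the activation times a half-wave-rectified
sinusoid at the respiration frequency (8 Hz, identified with the theta peak
of the LFP), scaled by `osn_gain` (70 mV at peak), plus a small constant
spontaneous drive (`osn_baseline`, 1% of the gain). The gain was chosen so
that odor-driven mitral cells fire robust respiration-locked bursts; the
spontaneous fraction was kept low because a larger pedestal (e.g. 5%) puts
the whole mitral population near threshold, makes all pyramidal cells
co-fire during learning and erases the odor specificity of potentiation —
at the cost that concentrations far below the mitral rheobase evoke no
bulb output at all (see Limitations).

What the generator emulates: columnar odor identity, graded activation,
respiration-locked input, concentration scaling, controlled overlap. What
it does not: receptor chemistry, sniff-to-sniff variability, mixtures,
adaptation in the periphery. Passing tests therefore speak to the circuit
mechanism, not to real odor statistics.

## Plasticity

Pyr→Pyr synapses start low (10⁻⁴) and potentiate between sniff cycles:
$w_{ij} \leftarrow w_{ij} + \alpha \, x_i x_j$, where $x_i, x_j$ are the
spike counts of the two cells over the just-completed cycle (half-open
window, update applied at the boundary), clipped at `weight_cap`.
Non-connections never change; no other class is plastic. The defaults
($\alpha$ = 3.5 × 10⁻⁴, cap 0.0075) are a calibration: $\alpha$ large
enough that five seconds of familiar-odor exposure under medium OXT
produces a clear, instantiation-consistent post-learning rate increase, the
cap low enough that the potentiated subnetwork amplifies its odor without
igniting the whole population (learning rate and learning duration trade
off, so other pairs of values reproduce the same phenomena). Plasticity is
enabled only during designated learning phases, not during the 0.5 s test
presentations.

## Protocols and analyses

`run_protocol()` scripts the experiments: single-cell characterization
(adaptation and rheobase curves), the learning experiment (0.5 s baseline /
familiar / novel tests under medium OXT, 5 s familiar-odor learning under a
given OXT level, re-tests; 10 instantiations × 3 OXT levels), population
distances, LFP spectra, spike accumulation and concentration series. Every
test presentation is preceded by a 250 ms blank settling period excluded
from analysis, and each instantiation draws a fresh network, fresh odors
and fresh spike randomness from its seed; the respiration clock runs
continuously across phases.

Rates are counted over whole 0.5 s presentations for all 100 pyramidal
cells. Distances are Euclidean norms between the 100-dimensional mean-rate
vectors, normalized by the mean pre-learning distance of the same
comparison where stated. The LFP is the per-step mean subthreshold
pyramidal potential (pre-reset values on spiking steps), a low-pass
electrode surrogate. Spectra are mean-subtracted Hann-windowed Welch
estimates with 500 ms segments and 50% overlap (2 Hz resolution; traces
under 2 s are analyzed as a single segment); band power is the mean
peak-normalized power over 12–30 Hz. The spectral-comparison protocol uses
4 s odor presentations around the learning phase, since 0.5 s windows only
contain four sniffs and their 2 Hz-resolution estimates are too noisy for
band comparisons. Paired pre/post contrasts use two-sided paired t-tests at
alpha 0.01; factorial contrasts use `stats::aov()`.

Problem sizes in the shipped tests and acceptance script: 10 cells for the
adaptation curve, one 5 s run for the pre-learning spectrum, 10
instantiations for the learning statistics, 4 for the beta comparison, 6
for distances, 12 s presentations for accumulation. These match the
reported replicate counts where the source states them and otherwise keep a
complete run in the minutes range on one core.

## Numerical choices and degenerate inputs

Forward Euler at 1 ms with the smallest membrane time constant (1 ms)
reaches exactly the steady state in one step — acceptable for a
drive-following input layer. The conductance update order (decay, drive,
integrate, spike, inject, reset) makes a spike's own kernel start at zero
on the spike step, as the kernel demands. Sniff boundaries are detected by
period-counter crossings with a 10⁻⁹ guard against floating-point
boundary drift. Degenerate statistics (zero-variance paired differences)
are flagged rather than tested; spectra refuse traces shorter than one
analysis window; configs with inverted thresholds, mis-ordered kernel time
constants, negative rates or unstable coupling are rejected at
construction.

## Known limitations

* **Novel-odor contamination.** Potentiation driven by spike-count products
  cannot be perfectly odor-specific: cells respond in a graded way, partly
  to both odors (shared in-degree, threshold jitter, block adjacency), so
  the novel odor's post-learning responses rise by a small fraction of the
  familiar effect. In paired testing over 10 instantiations this small
  shift is sometimes statistically detectable — the novel-odor "no change"
  control is the least robust of the reproduced findings.
* **Familiar–novel distance under strong learning.** Because post-learning
  gains to the familiar and the novel odor fall largely on the same
  strongly-connected cells, the familiar–novel difference vector does not
  reliably lengthen after learning, even where the baseline–familiar
  distance grows clearly.
* **Sub-rheobase concentrations.** At the default spontaneous drive the
  mitral threshold is a hard cliff: concentration ratios of a few percent
  evoke no bulb spikes, so no downstream amplification can reveal them.
  Raising `osn_baseline` to ~5% moves mitral cells against their threshold
  and restores a below-threshold detection effect, but sacrifices the
  specificity above; the concentration-series machinery supports either
  setting.
* **Beta magnitude.** The post-learning beta-band increase is consistent
  but modest relative to the dominant theta peak; the pre-learning beta
  "shoulder" reflects the 16/24 Hz harmonics of the rectified 8 Hz
  respiration drive.
* The model has no inhibition within the AON, no synaptic depression, no
  conduction delays, and a 1000 Hz output ceiling set by the per-step
  Bernoulli draw.
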