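Package: aonsim
Title: Spiking-Network Simulation of Odor Learning in the Anterior Olfactory Nucleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic leaky integrate-and-fire simulation of the olfactory
    bulb and anterior olfactory nucleus (AON) circuit, with conductance
    synapses, calcium-dependent spike-rate adaptation, oxytocin-modulated
    pyramidal-cell excitability, and sniff-cycle Hebbian plasticity among AON
    pyramidal cells. Includes synthetic odor stimulus generation under a
    respiration clock, scripted learning protocols, and the analyses used to
    characterise odor learning: firing-rate matrices, population-vector
    Euclidean distances, local field potential power spectra (theta/beta
    bands), spike-accumulation curves, adaptation and rheobase curves, and the
    supporting significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
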