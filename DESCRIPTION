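Package: blanet
Title: Biophysical Basolateral Amygdala Network Model with Basal Forebrain Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based 1000-cell network model of the basolateral
    amygdala (BLA) with two principal-neuron subtypes and three interneuron
    classes (PV+, SOM+, CR+), Hodgkin-Huxley multicompartment cell models,
    AMPA/NMDA/GABA-A synapses with short-term plasticity and cholinergic gain
    modulation, theta-modulated GABAergic basal-forebrain afferents,
    Ornstein-Uhlenbeck background conductances, and line-source reconstruction
    of the local field potential. Includes spectral and phase-entrainment
    analytics, the six-case rhythmicity-by-cholinergic-tone experiment suite,
    and interneuron-ablation experiments with firing-rate renormalization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
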