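Package: mfbrain
Title: Whole-Brain AdEx Mean-Field Network Models of Default Mode
    Network Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of whole-brain network dynamics built
    from conductance-based adaptive exponential (AdEx) integrate-and-fire
    mean-field models. Each brain region is an interacting pair of
    excitatory and inhibitory populations whose rate dynamics follow a
    fitted transfer function; regions are coupled through a directed,
    weighted connectome with tract-length transmission delays and separate
    excitatory-to-excitatory and excitatory-to-inhibitory routing. Includes
    a small AdEx spiking-network simulator used to fit and validate the
    mean field, generators for synthetic bilateral connectomes with a
    default-mode-like module and an insula-like hub, stimulation and
    excitation-inhibition perturbation experiments, parameter sweeps with
    failure-mode classification, and evoked-response statistics (epoching,
    pre/post deltas, exact Wilcoxon signed-rank tests, FDR correction,
    functional connectivity, hierarchical clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
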