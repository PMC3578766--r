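Package: stdpnet
Title: Network Structure from Spike-Timing Dependent Plasticity in Recurrent Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of leaky integrate-and-fire neurons whose
    excitatory-to-excitatory synapses are modified by pair-based spike-timing
    dependent plasticity (STDP) under five window regimes (balanced, potentiation-
    dominated, depression-dominated, rightward- and leftward-shifted), reduces the
    network to a two-synapse phase-plane model whose drift coefficients are computed
    numerically and validated against direct pair simulation, and quantifies the
    resulting network structure with closed-loop censuses via matrix-power traces,
    shuffle null models, a recurrence index, disconnected-pair counts and in-/out-hub
    degree analysis. Includes diagnostics for the asynchronous irregular operating
    regime (inter-spike-interval coefficient of variation and average pairwise
    cross-covariance) and experiment orchestration that reproduces the qualitative
    result surfaces at reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
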