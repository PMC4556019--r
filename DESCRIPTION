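Package: hubsync
Title: Hub-Mediated Synchronization of Kuramoto Oscillators on Structural Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coupled Kuramoto phase oscillators on binary structural
    connectomes and quantifies how high-degree hub (rich-club) nodes shape the
    transition from modular to whole-brain synchronization. Provides group
    consensus thresholding of subject-level connectivity matrices, degree-based
    hub selection, normalized rich-club coefficients against degree-preserving
    nulls, modularity-based module detection, a fixed-step Runge-Kutta
    integrator for the Kuramoto model, global and edgewise synchronization
    order parameters, trial-averaged synchronization probabilities, modular
    and hub mean-field influence decompositions, targeted hub-edge suppression
    and nodal frequency perturbation experiments, and generators for synthetic
    rich-club connectomes with planted modules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
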