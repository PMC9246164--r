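Package: netlesion
Title: Multi-Perturbation Lesion Analysis of Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the causal contribution of nodes and connections of a
    recurrent artificial neural network to its task performance by systematic
    perturbation. Implements single-element perturbation analysis (SPA),
    multi-perturbation Shapley value analysis (MSA) with a permutation-sampling
    estimator and coalition caching, pairwise causal interaction analysis
    (PCIA) with paradoxical-lesion (Sprague-effect) detection, lesion impact on
    functional connectivity (IFC), and bootstrap significance testing. Ships a
    synthetic ground-truth network containing an inhibitory self-loop motif
    that produces a paradoxical lesion effect, together with a winner-take-all
    surrogate task and control-network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
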