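Package: ribodyn
Title: Condition-Specific Translation Elongation Dynamics from Ribosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates typical codon decoding rates (TDR) from codon-resolution
    ribosome footprint count profiles by maximum-likelihood fitting of
    exponentially modified Gaussian distributions to normalized footprint count
    histograms, and derives per-gene mean typical decoding rates (MTDR) and
    standardized scores across time points. Includes codon-usage indices (tAI,
    CAI adaptation groups), dynamic codon demand, rank-based coefficient of
    variation statistics, a stochastic TASEP translation simulator with a
    finite shared ribosome pool and synonymous-recoding experiments,
    initiation-rate inference by binary search against simulated ribosome
    occupancy, MTDR co-score network statistics, and a synthetic ribo-seq data
    generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
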