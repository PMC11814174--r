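Package: popsep
Title: Population Decoding and Category Separation for Trial-Aligned Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying visual category information carried by
    populations of inferior temporal cortex neurons recorded during passive
    fixation. Provides per-neuron visual-responsiveness classification
    (paired t-tests with Benjamini-Hochberg false-discovery-rate control),
    Gaussian-kernel firing-rate functions, trial-averaged population vectors
    over sliding time windows, cross-validated logistic-regression decoding
    time courses, Fisher linear-discriminant projections with Mahalanobis
    category-separation time courses, the between-area and between-session
    statistical comparisons built on them, and an inhomogeneous-Poisson
    spike-train simulator whose generative parameters are recoverable by the
    analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
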