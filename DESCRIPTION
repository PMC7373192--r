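Package: replinoise
Title: Replicate Concordance Diagnostics for Low-Biomass 16S rRNA Gene Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether a low-biomass 16S rRNA gene
    sequencing result represents reproducible biological signal, reagent
    contamination, or stochastic sequencing noise. Implements Bray-Curtis
    partitioning of technical-replicate distances into intra- and
    inter-replicate sets with bounded-support kernel density estimates, a
    regime classifier built on those summaries, a logistic fit of the
    bacterial-biomass versus reproducibility transition, mean-of-replicate-
    medians consensus profiles, contaminant OTU identification from negative
    controls with read-retention accounting, a permutational MANOVA on
    distance matrices, and a generative simulator of the read-competition
    noise process observed in dilution-series experiments.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
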