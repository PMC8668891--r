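Package: abctrio
Title: Three-Population Demographic Inference with Coalescent Simulation
    and ABC Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical demographic inference for trios of closely related
    species from multi-locus RAD-like data. Simulates a generalist
    three-population divergence model with epoch-restricted migration
    (ancestral migration versus secondary contact, and every pattern of gene
    flow with the outgroup species), per-lineage size changes, and optional
    linked-selection heterogeneity of effective size and migration rate along
    the genome. Summarises datasets with a fixed vector of within- and
    between-species statistics (nucleotide diversity, Watterson's theta,
    Tajima's D, gross and net divergence, FST, site-pattern counts and
    Patterson's D), performs random-forest model choice with out-of-bag
    calibrated posterior probabilities and random-forest parameter
    estimation, and ships a synthetic pseudo-observed data generator with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    ape,
    vcfR,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
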