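Package: tempogen
Title: Temporal Mitogenome Diversity, Serial Coalescent Simulation and
    Approximate Bayesian Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the loss of mitochondrial genetic
    diversity between dated sample layers (e.g. museum skins versus modern
    blood samples) and for inferring the demographic history that produced
    it. Provides per-layer diversity statistics (haplotype and nucleotide
    diversity, Tajima's D, and an exact big-integer evaluation of Fu's Fs
    via the Ewens sampling formula), a heterochronous coalescent simulator
    for piecewise-constant haploid demographies, a synthetic-data generator
    for study-shaped datasets, approximate Bayesian computation with local
    linear regression adjustment and logistic model choice including
    pod-based type I/II error rates, and temporal and minimum-spanning
    haplotype networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
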