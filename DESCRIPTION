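Package: tscevo
Title: Evolution of Supercoiling-Mediated Gene Regulation on Circular
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Individual-based evolutionary simulator of the coupling
    between gene transcription and DNA supercoiling on circular
    bacterial chromosomes. Gene expression is the fixed point of a
    supercoiling-mediated interaction system (twin-domain model):
    transcription of a gene perturbs the local supercoiling at
    neighboring promoters, which in turn modulates their opening
    probability and expression. Populations of genomes evolve by genomic
    inversions under fitness-proportional selection in two environments
    that shift the global supercoiling level in opposite directions. The
    package also provides the post-hoc analysis toolkit: activation
    censuses, environmental supercoiling sweeps, oriented gene-pair and
    canonical gene-triplet censuses, minimal contiguous subnetwork
    sizes, and knockout-derived effective interaction graphs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
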