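Package: mitocong
Title: Phylogenetic Congruence Analysis of Mitochondrial Gene Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of phylogenetic incongruence among the 13
    protein-coding and 2 ribosomal RNA genes of animal mitochondrial genomes.
    Generates partitioned mitogenome alignments with controllable congruence
    structure, fits per-gene maximum-likelihood trees under a TIM2+G+I
    substitution model with a Felsenstein pruning engine, and compares gene
    partitions with RELL-based topology tests (bp-RELL, KH, SH, weighted KH/SH,
    expected likelihood weights, approximately unbiased test) and the
    parsimony-based incongruence length difference test. Congruence workflows
    cover pairwise gene-by-gene matrices, leave-one-out "antigene" comparisons,
    functional-category comparisons, and taxon-subsampling experiments, plus
    regression of per-gene congruence counts on distance from the origin of
    replication on each strand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
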