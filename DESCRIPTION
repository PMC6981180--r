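Package: vdjrep
Title: Simulation and Comparative Analysis of Antibody V(D)J Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of adaptive immune receptor
    repertoire (AIRR-seq) data: reading and writing annotated rearrangement
    tables in the AIRR TSV dialect, germline gene set handling, a generative
    V(D)J recombination simulator with species presets and ground-truth
    output, annotation-based inference of factorized recombination models
    with exact event-level and complete Kullback-Leibler divergences,
    gene-segment usage profiling with z-score heatmap clustering, CDR3 and
    junction statistics, incidence-based (Chao2) and abundance-based (Chao1)
    clonotype diversity estimation with rarefaction, and public-clonotype
    sharing analysis including Venn-region decompositions and CDR3 sequence
    logos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
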