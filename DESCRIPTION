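Package: genustax
Title: Genome-Based Genus Demarcation from Orthologous Clusters,
    Similarity Matrices and Core-Genome Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A pipeline for genome-based prokaryotic taxonomy: reciprocal
    best-hit orthologous clustering of proteomes, genome similarity
    matrices (average amino-acid identity, fragment-based orthologous
    average nucleotide identity, percentage of conserved proteins), a
    concatenated single-copy core-genome phylogeny with patristic
    evolutionary distances, statistical comparison of the metrics, and a
    threshold-plus-monophyly partition of genomes into genera.  A seeded
    pan-genome simulator with known gene families, tree and genus labels
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    igraph,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
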