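Package: igsclust
Title: Structure-Based Clustering of Bacterial Intergenic Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide extraction and classification of bacterial
    intergenic sequences (IGSs). Extracts equal-length upstream sequences
    anchored at Shine-Dalgarno-derived transcription start sites from a
    GenBank or FASTA/GFF3 annotation, scores all pairs by global alignment
    with free end gaps (EDNAFULL, affine gaps), thresholds the similarity
    matrix against sequence-shuffling nulls, clusters with the normalized
    Laplacian / eigengap / k-means spectral pipeline, validates clusters
    with silhouettes, characterizes them by positional base composition
    and homogeneous A/T/AT segment statistics, and associates clusters
    with interaction-network and functional-category features using
    resampling nulls and exact binomial tests. Includes a synthetic
    genome simulator with planted operons, Shine-Dalgarno motifs,
    compositional classes and network modules for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
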