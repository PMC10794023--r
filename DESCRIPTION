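Package: omapsv
Title: Structural Variant Calling from Optical Genome Mapping of Heterogeneous Tumor Samples
Version: 0.1.0
Authors@R:
    person("OMAPSV", "Developers", email = "omapsv@example.org", role = c("aut", "cre"))
Description: Calls structural variants from nano-channel optical genome
    mapping data of cancer samples, where tumor purity, sub-clones and copy
    number changes make the fraction of SV-supporting molecules at a locus
    unpredictable. Provides an indel pipeline based on cross-molecule
    arbitration of abnormal inter-label distances, pooling of distances into
    candidate regions and constrained one-dimensional model-based clustering
    with no prior on allele fraction; a complex-SV pipeline based on
    split-alignment junction classification, targeted re-alignment of
    unaligned molecule parts and break-point consolidation; readers and
    writers for the BNX/CMAP/XMAP optical mapping formats plus in-silico
    digestion; a cancer-aware simulator (clone evolution graph, cell
    mixtures, configurable noise) with ground-truth output; and benchmarking
    utilities (precision/recall/F1, zygosity-aware matching, per-stage
    stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
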