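Package: SymbiontErosion
Title: Comparative Genome-Erosion Analysis for Reductively Evolving Endosymbionts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying differential genome erosion between
    closely related endosymbiont genomes. Implements branch-specific
    non-synonymous substitution rate (dN) estimation on a fixed species
    topology by Nei-Gojobori (1986) codon-site counting over weighted
    parsimony ancestral reconstructions, branch-ratio standardization of
    per-gene dN against a free-living sister lineage, pathway-level
    relaxation-of-constraint tests, a paired dN-difference test between two
    endosymbiont lineages, and rule-based pseudogene detection via a
    frameshift-aware protein-to-DNA alignment. A codon-level sequence
    simulator with per-branch dN/dS and a genome fabricator with injected
    gene lesions provide ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
biocViews: Phylogenetics, Genetics, SequenceMatching, Alignment,
    ComparativeGenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
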