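Package: taarevol
Title: Molecular Evolution Analysis of Trace Amine-Associated Receptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline for studying the
    evolution of chemosensory receptor gene families such as the trace
    amine-associated receptors (TAARs). Provides translated homology mining of
    genome scaffolds with Karlin-Altschul E-values and reciprocal verification,
    gene-model classification into intact genes, incomplete models and
    pseudogenes, signature-motif grammar scanning, hydropathy-based
    transmembrane topology prediction with Ballesteros-Weinstein numbering,
    neighbor-joining phylogenetics with JTT+Gamma maximum-likelihood distances
    and bootstrap supports, a Goldman-Yang codon-model likelihood engine (site,
    branch and branch-site models, likelihood-ratio tests, empirical-Bayes
    site identification), TreeSAAP-style tests of destabilizing selection on
    amino-acid physicochemical properties, and a gene birth-death plus
    codon-evolution simulator that supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
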