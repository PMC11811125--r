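Package: bfbscope
Title: Detection and Reconstruction of Breakage-Fusion-Bridge Amplicons
    from Optical Genome Map Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and reconstructs breakage-fusion-bridge (BFB) focal
    amplifications from label-level copy-number and foldback structural-variant
    evidence abstracted from optical genome mapping. Provides the BFB string
    grammar and enumeration of candidate amplicon architectures matching an
    observed copy-number vector, weighted circular binary segmentation of the
    per-label copy-number signal, candidate-region selection from amplification
    and foldback-enrichment filters, a Gibbs-refined discrepancy score that
    classifies amplicons as BFB-positive or negative, simulators for BFB and
    non-BFB (ecDNA-like and chromothripsis-like) focal amplifications with a
    benchmarking harness, and auxiliary statistics for fragile-region and
    break-dispersion analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
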