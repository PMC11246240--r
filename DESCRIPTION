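Package: paleodup
Title: Duplication-Mode Classification, Ks-Based Paleopolyploidy Dating,
    and Duplicate-Retention Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how whole-genome duplications (WGD) shape
    gene families and metabolic pathways. Classifies paralog pairs into
    WGD, tandem, proximal, transposed and dispersed duplications from
    intra-genomic collinearity on gene-rank coordinates; estimates Ka/Ks
    per pair by Nei-Gojobori (1986) counting with Jukes-Cantor correction;
    decomposes the Ks distribution into Gaussian mixture components on the
    log10 scale to identify paleopolyploidy peaks and assign WGD pairs to
    epochs; tests pathway-versus-genome WGD-retention enrichment,
    term over-representation and cross-species group differences; and
    profiles WGD retention across rank-neighborhoods of focal genes with a
    permutation null. A genome-evolution simulator with nested WGDs,
    biased pathway retention, small-scale duplications and sequence
    divergence to target Ks provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    mclust,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
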