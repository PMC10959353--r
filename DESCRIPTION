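Package: mobiloscope
Title: Simulation and Detection of Mobile LTR Retrotransposons from Mobilome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify long terminal repeat (LTR) retrotransposon
    abundance across accession panels and to detect transposition-competent
    families from mobilome sequencing of extrachromosomal circular DNA
    (eccDNA). Implements proxy copy-number estimation from normalized
    all-hits read coverage, random-intercept mixed models with marginal R2
    for environmental associations, tail-to-head 2-LTR junction libraries
    with junction-spanning read detection and genomic-background controls,
    circle-forming region discovery from assembled mobilome contigs with
    stress/genotype specificity classification, filtering of transposon
    insertion polymorphisms against shared backgrounds with clipped-read
    zygosity statistics, and extraction of GWAS candidate windows and gene
    sets. Ships a fully ground-truthed synthetic mobilome generator
    (families, genomes with target-site duplications, eccDNA pools,
    rolling-circle amplified reads, accession panels) so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
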