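Package: wgabias
Title: Quantifying Whole-Genome-Amplification Bias in Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the bias that whole-genome amplification (WGA)
    introduces into targeted amplicon sequencing of FFPE tissue. Implements
    MLPA-style depth-ratio gene-copy-number (GCN) normalization, variant
    filtering on depth/VAF/DP4, delta-VAF biased-variant classification
    (germline, somatic, WGA-created), substitution-spectrum counting with a
    two-count z-test, replicate VAF noise estimation, and a synthetic-data
    generator that emulates a paired frozen/FFPE, non-WGA/WGA amplicon study
    design so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
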