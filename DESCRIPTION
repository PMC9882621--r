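Package: mitohet
Title: Mitochondrial DNA Copy Number, Heteroplasmy and Length-Variant Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying mitochondrial DNA (mtDNA) copy number and
    heteroplasmy from whole-genome sequencing reads using a per-sample
    self-reference consensus with coordinate liftover back to the canonical
    reference, NUMT-aware read placement, dual-pass (primary plus shifted)
    variant calling across the circular control region, post-calling variant
    and sample quality control, poly-C length-heteroplasmy genotyping at the
    CSBII locus (bulk and single cell), construction of covariate-corrected
    analysis phenotypes, and a summary-statistics layer covering fixed-effect
    meta-analysis with heterogeneity, LD clumping and locus definition,
    effect-size regression, binary-genotype PCA, colocalization, fine-mapping
    enrichment and gene assignment. Ships deterministic synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    splines,
    nnet,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
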