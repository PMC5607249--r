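Package: cnvburden
Title: Rare Copy-Number-Variant Burden Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rare copy-number-variant (CNV) case-control
    analysis from segment-level array CNV calls: probe-count, size and
    blacklist-region quality filters; clustering of calls into loci by the 80
    percent reciprocal-overlap rule; carrier-frequency based rarity selection;
    stratified case-control burden comparison with a two-sample Poisson-rate
    likelihood-ratio chi-square test and Bonferroni-controlled significance;
    hot-spot and pathogenic classification of rare CNVs against curated region
    sets; trio-based inheritance (maternal, paternal, de novo) calling; and
    two-hit carrier detection. Includes a synthetic cohort and trio generator
    calibrated to published autism spectrum disorder case-control CNV rates so
    that every stage is testable without access to raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
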