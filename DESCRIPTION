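Package: stresschip
Title: ChIP-Chip Binding Sites, Stress-Response Expression, and Growth
    Fitness in the Fission Yeast Oxidative Stress Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing the transcriptional
    response of Schizosaccharomyces pombe to hydrogen peroxide through the
    Sty1-Atf1/Pcr1 pathway. Calls significantly enriched regions (SERs) on
    two-channel tiling-array ChIP-chip tracks using a robust
    median-absolute-deviation threshold and a windowed binomial test;
    classifies binding sites as major or minor across conditions and
    factors and assigns them to probable promoters; discovers the enriched
    DNA-binding motif from apex-centred sequences with an MDscan-style
    search and evaluates it by ROC; calls H2O2-responsive genes and their
    Atf1/Pcr1 dependency from replicated expression time courses with a
    SAM-style permutation statistic and a consecutive-time-point rule;
    scores growth-fitness defects from mini-culture growth curves (T50,
    delta-T50, deficient score); and integrates the layers into ranked
    report tables with exact-test enrichment statistics. A seeded
    synthetic-data generator emulates the tiling-array design, planted
    binding sites, expression time courses and logistic growth curves so
    the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
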