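Package: diurnal
Title: Circadian Rhythm Detection and Reprogramming Analysis for
    Multi-Condition Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric detection of circadian rhythmicity in gene
    expression time courses via a from-scratch JTK_CYCLE implementation
    with exact conditional null distributions for the tied Kendall
    statistic, replicate-level Dixon Q outlier pruning, low-expression
    filtering, rhythm-set comparison across conditions (exclusive,
    common and de novo oscillators; phase histograms; amplitude
    taxonomy; phase-sorted heatmap matrices), promoter-window
    transcription-factor binding-site enrichment with motif-quality
    filters and a cross-condition meta-analysis that flags
    condition-exclusive regulators, ChIP-supported target-set
    construction, and a seeded synthetic-data generator that emulates a
    four-condition, six-timepoint, three-replicate circadian study
    design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
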