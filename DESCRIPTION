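Package: nemamorph
Title: Quantitative Muscle Morphometry, Locomotion and Synaptic Phenotyping for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative phenotyping of Caenorhabditis
    elegans disease models. Segments GFP-labelled body-wall-muscle myosin fibres from
    calibrated fluorescence images, skeletonizes them and measures per-fibre branch
    lengths and the gap-to-cell-area ratio; counts swimming thrashes and crawling body
    bends from posture time series and computes centroid speeds, population activity
    counts and levamisole contraction/paralysis read-outs; detects spontaneous
    postsynaptic currents in voltage-clamp traces; and compares genotypes with a
    one-way ANOVA/Dunnett, variance F-test and chi-square/FDR battery. A seeded
    synthetic-data module generates every input type with known ground truth so each
    stage has a parameter-recovery test surface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
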