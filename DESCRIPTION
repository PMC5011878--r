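Package: rhizoslide
Title: Image Analysis and Split-Nitrogen Trial Statistics for Rhizoslide Root Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paper-based rhizoslide root phenotyping
    platforms. Fuses dual-illumination root images by per-pixel minimum tonal
    value, segments maize shoots from blue-background images with a two-step
    excess-green (2G - R - B) threshold plus Otsu refinement, ingests traced
    root systems from RSML files, extracts crown-root length series and
    branching-zone lateral-root traits, fits linear growth models to root and
    shoot series, and analyses split-nitrogen genotype trials with a linear
    mixed model allowing heterogeneous residual variances per nitrogen level
    (REML), BLUPs, Tukey HSD, and per-treatment mean-based heritability.
    Includes seed-deterministic generators for synthetic root/shoot scenes,
    RSML traces, growth series and trial trait tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    png,
    jsonlite
Suggests:
    tiff,
    nlme,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
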