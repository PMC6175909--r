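Package: acrquant
Title: Quantification Toolkit for Soma-Targeted Optogenetic Silencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantification stack for optogenetic silencing studies
    with anion-conducting channelrhodopsins: freezing-behavior classification
    from pixel-change video traces, per-unit extracellular silencing and
    antidromic-spike analysis, photocurrent closing kinetics and light-power
    saturation (EPD50) fits, analytical light propagation in brain tissue with
    depth-dependent wavelength optimization, hemispheric c-Fos/DAPI
    lateralization ratios, and self-contained implementations of the
    rank-based and contingency statistics used throughout (including the
    Scheirer-Ray-Hare two-way rank ANOVA). Synthetic-data generators emulate
    each input modality so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
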