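Package: srmquant
Title: Targeted SRM Metabolite Quantitation, Method Validation and Cohort Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the data-processing chain of targeted UHPLC-MS/MS
    (selected reaction monitoring) metabolite panels: transition-panel
    management, internal-standard normalization of peak areas, 1/x-weighted
    linear calibration with limit-of-detection and linear-range (LLOQ/ULOQ)
    determination, intra- and inter-day repeatability reporting,
    confound-minimizing balanced cohort subsampling, and per-metabolite
    mixed-effects association analysis with Benjamini-Hochberg false
    discovery rate control. Includes a ground-truthed synthetic data
    generator emulating calibration series, quality-control replicates and
    a clinical cohort with technical triplicates, so the full pipeline can
    be exercised and verified without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
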