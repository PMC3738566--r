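Package: dscrepro
Title: Reproducibility Analysis of DSC Perfusion MRI Tumor Blood-Volume Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for dynamic susceptibility contrast (DSC)
    perfusion MRI cerebral blood volume analysis in brain tumors: a seeded 4D
    digital phantom with labeled tissue compartments and simulated observer
    delineations, signal-to-concentration conversion, gamma-variate first-pass
    fitting, two-parameter contrast-leakage correction, relative and normalized
    CBV mapping under manual (contralateral white-matter ROI) and automatic
    normalization, rigid mutual-information coregistration, manual per-slice ROI
    and semiautomatic EM Gaussian-mixture segmentation of tumor masses, and
    intra-/interobserver reproducibility statistics (ICC with 95% CI,
    coefficient of variation, Bland-Altman limits of agreement, paired t-test,
    Kolmogorov-Smirnov normality), with a study runner that executes the full
    2 observers x 2 sessions x 2 methods x 2 structural-image design on
    synthetic cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
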