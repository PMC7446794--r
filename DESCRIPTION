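Package: ramscreen
Title: Raman Chemometric Urinalysis Screening with PCA-Based Discriminant Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric screening pipeline for liquid-urine Raman spectra:
    spectral truncation, iterative asymmetric polynomial (Goldindec-style)
    baseline correction, vector normalization and replicate averaging;
    principal component analysis followed by discriminant analysis of
    principal components (DAPC) with leave-one-out screening evaluation
    (accuracy, sensitivity, specificity, PPV, NPV); the total principal
    component distance (TPD) statistic with one-way ANOVA and Tukey HSD
    group comparisons; extraction of per-wavenumber contributions to the
    class separation with molecular band assignment; and a synthetic
    urine-cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
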