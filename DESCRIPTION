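Package: nmrelp
Title: Extended Lipid Panel Quantification from Serum 1H-NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to calibrate and deploy an NMR-based extended lipid panel:
    partial least squares (PLS1) regression models that predict total
    cholesterol, triglycerides, HDL cholesterol and apolipoprotein B from the
    lipid methyl/methylene region (0.494-1.592 ppm, 1600 points) of serum
    proton NMR spectra. Includes leave-one-out cross-validation for latent
    variable selection, DFFITS-based training outlier removal, a
    triglyceride-routed pair of HDL-C models, NIH-equation LDL-C and
    non-HDL-C derivation with reportable-range censoring, a synthetic serum
    spectrum generator for end-to-end testing, and the clinical validation
    statistics battery (precision, sensitivity limits, linearity, Deming
    method comparison, bias, interference, stability, collection-tube
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
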