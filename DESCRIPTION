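Package: dectbmd
Title: Phantomless Dual-Energy CT Volumetric Bone Mineral Density Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-energy material decomposition of paired 90/Sn150-kVp CT
    volumes into trabecular matrix and adipose volume fractions and
    volumetric bone mineral density (BMD, mg/cm3), with tools to define and
    erode three-dimensional trabecular volumes of interest, a synthetic
    generator for dual-energy phantoms and fracture-outcome patient cohorts,
    and the downstream fracture-risk diagnostic-accuracy analysis: empirical
    ROC curves with Youden-optimal cut-offs, exact binomial diagnostic
    metrics, and multivariable logistic regression with odds ratios and
    Nagelkerke R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
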