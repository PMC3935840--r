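Package: neoresponse
Title: Quantitative CT Texture and Histogram Analysis of Neoadjuvant
    Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor response to neoadjuvant therapy from paired
    pre/post-treatment CT: first-order features (volume, density, mass,
    attenuation-histogram skewness and kurtosis) and gray-level size-zone
    matrix (GLSZM) texture features (intensity variability, size-zone
    variability) extracted from segmented tumors, followed by percent-change
    response statistics with pathologic-response labelling, univariate
    screening, backward-stepwise logistic regression with likelihood-ratio
    removal, and ROC analysis with Youden-optimal cutoffs. Includes a
    seedable synthetic paired-tumor cohort generator for end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
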