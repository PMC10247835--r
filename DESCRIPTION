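Package: rotadebulk
Title: Predicting the Debulking Effect of Rotational Atherectomy from
    Intravascular Imaging Cross-Sections
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric prediction of the tissue ablated by a rotational
    atherectomy burr from pre-procedural intravascular (OCT/OFDI)
    cross-sections.  Builds predicted, actual and overlap ablation regions
    by polygon clipping, scores them per frame as percent-correct and
    percent-error areas and angles, integrates them into lesion-level
    volumes, classifies frames into four prediction-quality groups by a
    cohort median split, and runs the accompanying statistics: a
    univariable screen feeding a multivariable logistic regression with
    odds ratios, an ROC cutoff for the catheter-wire clearance, and
    contact-stratified comparisons of catheter-based versus wire-based
    prediction.  Includes a seeded synthetic vessel cross-section
    generator with ground truth for validation, since the clinical images
    the method was developed on are not shareable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    polyclip,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
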