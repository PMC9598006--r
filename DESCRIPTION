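Package: ifsat
Title: Infant Facial Skin Assessment Tool Scoring and Validation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Infant Facial Skin Assessment Tool (IFSAT), a
    caregiver-usable grid of four binary skin symptoms (erythema, papules,
    dryness, exudate/yellow scaling) over nine facial areas, together with
    its three scoring methods (original unit-weight count and two weighted
    versions). Provides from-scratch implementations of the statistical
    procedures used to validate such severity instruments: the
    Jonckheere-Terpstra trend test with tie correction and exact
    permutation option, empirical ROC curves with tie-adjusted AUC and
    Youden-index cutoff selection, two-way intraclass correlation
    coefficients with F-based confidence intervals, Mann-Whitney U with
    exact small-sample p-values, Spearman rank correlation and binary
    agreement rates. A latent-severity cohort simulator generates
    study-like infant cohorts (rater noise, cure-period censoring,
    skin-barrier readings) so the full reliability and validity pipeline
    can be exercised and property-tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
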