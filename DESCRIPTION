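Package: wmpredict
Title: Seizure-Outcome Prediction from White-Matter Morphometry with
    Nested Leave-One-Subject-Out SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of smoothed white-matter
    tissue-probability volumes for pre-surgical prediction of seizure
    outcome after epilepsy surgery. Implements Fisher-criterion voxel
    ranking inside nested leave-one-subject-out cross-validation of a
    linear soft-margin support vector machine, balanced posterior
    accuracy with beta-posterior credible intervals, ROC and
    precision-recall curves, back-projection of SVM weights into voxel
    space with hemispheric lateralization chi-square tests, and the
    accompanying clinical covariate statistics (Fisher's exact,
    Mann-Whitney U, Kruskal-Wallis, Spearman). Ships a synthetic cohort
    generator that plants group-discriminative clusters in spatially
    smooth volumes so the whole pipeline is testable end to end, plus
    published per-patient decision-value fixtures for exact evaluation
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
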