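Package: mindmodal
Title: Multimodal Digital Biomarkers for Depression, Anxiety and Suicide-Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurization and evaluation pipeline for structured mental-health
    interviews recorded by a multimodal dialog system. Computes clinical
    speech-acoustic measures (percent pause time, F0 statistics, jitter,
    shimmer, harmonics-to-noise ratio), facial-landmark kinematics (mouth
    geometry, articulator velocity/acceleration/jerk, blink rate, eyebrow
    displacement) and TF-IDF text features per interview task; screens
    features with Kruskal-Wallis tests and Cohen's d effect sizes; and
    evaluates logistic-regression and linear-SVM classifiers of depression,
    anxiety and suicide risk under leave-one-subject-out cross-validation
    with fold-nested preprocessing and feature selection, including feature-
    and decision-level fusion. A synthetic-cohort generator with plantable
    group effects makes every stage testable without confidential clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
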