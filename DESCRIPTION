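Package: ionsig
Title: Ion-Channel Gene-Signature Risk Scoring and Survival Analysis in Lung Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds and evaluates sign-weighted gene-expression risk
    signatures for lung adenocarcinoma, centred on a 37-gene ion-channel
    signature. Provides paired and two-group differential-expression
    screening with Benjamini-Hochberg correction, standardized risk
    scoring with median dichotomization, Kaplan-Meier and Cox
    proportional-hazards survival stratification, a random-signature
    resampling null for signature non-randomness, cross-cohort
    reproducibility statistics (P-value and fold-change correlation, PCA,
    Ward/Manhattan clustering, stage-distribution chi-square), and a
    synthetic-cohort generator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
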