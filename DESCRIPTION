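Package: phrglycemia
Title: Continuous Personal Health Record Use and HbA1c Trajectories in
    Diabetes Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrospective-cohort analysis pipeline for studying the
    effect of continuous mobile personal health record (PHR) engagement on
    glycemic control. From raw app-usage logs and electronic medical
    record extracts it builds a diabetes cohort, classifies continuously
    engaged users from blood-glucose diary events, scores the diabetes
    complications severity index (DCSI) from ICD-10 diagnoses, fits
    per-patient HbA1c trend lines and the span-normalised 'decline'
    statistic, and runs the group-comparison and covariate-adjustment
    battery (t/Wilcoxon/median/z/chi-square tests, ANCOVA, logistic
    regression). A synthetic-data generator with known ground truth
    stands in for hospital data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
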