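Package: ogrs
Title: Optimized Genetic Risk Scores for Metabolically Unhealthy Obesity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs and evaluates optimized genetic risk scores (oGRS)
    that discriminate metabolically unhealthy from metabolically healthy
    obesity. Provides phenotype classification by combined Wildman/Meigs
    criteria (including HOMA-IR and cohort-relative percentile cut-offs),
    per-SNP inheritance-model selection (codominant, dominant, recessive)
    by adjusted logistic regression, greedy p-value-ordered SNP selection
    into an unweighted risk score, tertile risk-group stratification,
    ROC/AUC analysis with DeLong paired comparisons and minimal-subset
    search, Cox proportional-hazards age-of-onset modelling,
    Jonckheere-Terpstra trend tests, and a synthetic cohort generator that
    emulates the statistical structure the analysis assumes, so the whole
    pipeline is testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    optparse
Config/testthat/edition: 3
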