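# ogrs — optimized genetic risk scores for metabolically unhealthy obesity

Obese adults (BMI ≥ 30 kg/m²) split into a *metabolically healthy* (MHO)
phenotype — normal blood pressure, lipids and glucose homeostasis — and a
*metabolically unhealthy* (MUO) one. `ogrs` is an R implementation of a
complete workflow for asking how much common genetic variation separates
the two, aimed at biostatisticians and genetic epidemiologists who want
the procedure as reusable, tested functions rather than a one-off
analysis:

1. **Phenotype classification** by the union of the Wildman (> 1 of 9
   criteria) and Meigs (> 2 of 6 criteria) rules, including HOMA-IR
   (insulin × glucose / 22.5) and cohort-relative 90th-percentile
   thresholds over the obese stratum.
2. **Inheritance-model selection** per SNP: genotypes are coded
   codominant (0, 1, 2), dominant (0, 2, 2) or recessive (0, 0, 2) in
   risk-allele copies, and the adjusted logistic fit
   `status ~ code + age + sex + education` with the lowest SNP-term Wald
   p (ties: higher Cox & Snell R²) chooses the model.
3. **Greedy score optimization**: candidates enter in ascending-p order
   and are kept only if the score term's p-value strictly improves —
   the *optimized genetic risk score*
   `oGRS = Σᵢ Gᵢ`, an unweighted sum of the per-SNP codes.
4. **Risk stratification and inference**: tertile risk groups with exact
   binomial prevalence CIs and Jonckheere–Terpstra trend tests, ROC/AUC
   with DeLong paired comparisons and a minimal-SNP-subset search, Cox
   proportional-hazards modelling of age at survey (MUO = event,
   MHO = censored, Efron ties), score-by-BMI interaction models, and the
   rank-based two-step inverse-normal transform for non-normal
   biomarkers.
5. A **synthetic cohort generator** (Hardy–Weinberg genotypes, a centred
   logistic liability with 19 causal SNPs of mixed inheritance modes,
   biomarkers calibrated to published group-conditional means) so the
   whole pipeline is testable without access to individual-level study
   data.

The methods vignette (`vignettes/ogrs-methods.Rmd`) documents the models,
the defaults and every design decision in detail.

## A worked example

```r
library(ogrs)
cfg <- simulation_config(n_subjects = 398, seed = 7)   # study-scale obese cohort
report <- run_pipeline(pipeline_config(simulation = cfg, seed = 7))
print(report)
#> oGRS pipeline report
#>   cohort: n = 398 (MHO 74 / MUO 324, prevalence 81.4%)
#>   selected SNPs: 34; score OR = 1.42, p = 5.16e-16
#>   AUC: oGRS 0.826 | 7-SNP subset 0.736 | conventional 0.666 | conv+oGRS 0.859
#>   risk-group MUO prevalence: 59.2% / 91.9% / 96.3% (trend p = 1.25e-15)
```

Reading the output: of 398 simulated obese subjects, 81.4% are classified
metabolically unhealthy (the generator is calibrated to the ~80%
prevalence reported for obese adults). The greedy pass keeps 34 of the
67 candidate SNPs; each additional score point multiplies the adjusted
odds of MUO by 1.42. The full score discriminates MHO from MUO with an
apparent AUC of 0.83 — better than the conventional factors (age, sex,
education, BMI; AUC 0.67) alone, and 0.86 combined with them. The
smallest prefix of the selection order whose discrimination is not
significantly worse than the full score (DeLong p above the
Bonferroni-corrected threshold) has 7 SNPs. MUO prevalence climbs from
59% in the low-risk score tertile to 96% in the high-risk tertile. All
AUCs here are in-sample; the report's `overfit_guard` section carries a
split-half train/test gap (0.39 for this run — the greedy selection
overfits at n = 398, which is exactly why the guard exists), and
`cv_auc()` provides cross-validated alternatives.

Each stage is also a plain function (`classify_cohort()`,
`select_models()`, `rank_snps()`, `optimize_grs()`,
`assign_risk_groups()`, `delong_test()`, `cox_ph_fit()`,
`jonckheere_terpstra()`, ...) and a thin CLI wrapper is included:

```sh
Rscript inst/cli/ogrs-pipeline.R --config inst/extdata/demo_config.yaml --seed 5
```

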