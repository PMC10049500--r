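---
title: "Optimized genetic risk scores for metabolically unhealthy obesity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimized genetic risk scores for metabolically unhealthy obesity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogrs)
```

## The scientific problem

A subset of obese adults (BMI $\ge$ 30 kg/m$^2$) shows none of the usual
cardiometabolic abnormalities — normal blood pressure, lipids and glucose
homeostasis. This *metabolically healthy obesity* (MHO) phenotype contrasts
with *metabolically unhealthy obesity* (MUO), and the genetic factors that
separate the two are of direct interest for risk stratification: an
inexpensive germline score measured once could flag obese individuals
likely to deteriorate.

`ogrs` implements a complete, reproducible version of one workflow for
this question: classify subjects as MHO/MUO from clinical criteria, choose
a per-SNP inheritance model by adjusted logistic regression, build an
*optimized genetic risk score* (oGRS) by greedy p-value-ordered selection,
stratify the cohort into tertile risk groups, and quantify discrimination
(ROC/AUC with paired DeLong comparisons), age-of-onset association (Cox
regression) and trend/interaction structure. Because individual-level
study data of this kind are typically available only on request, the
package ships a synthetic cohort generator that reproduces the statistical
structure the analysis assumes, so every stage is testable end to end.

## Phenotype classification

Metabolic status is assigned by the union of two established criterion
sets. The *Wildman* rule counts nine binary criteria — elevated blood
pressure (SBP $\ge$ 130 or DBP $\ge$ 85 mmHg), BP medication,
TAG $\ge$ 1.7 mM, low HDL-C (< 1.0 mM in men, < 1.3 mM in women),
lipid-lowering medication, fasting glucose $\ge$ 5.6 mM, anti-diabetic
medication, HOMA-IR at or above the cohort's 90th percentile, and CRP at
or above the cohort's 90th percentile — and flags a subject when **more
than one** criterion is met. The *Meigs* rule counts six criteria (the
shared BP/TAG/HDL/glucose items, BP medication, and waist circumference
**strictly greater** than 102 cm in men / 88 cm in women) and flags when
**more than two** are met.

Design choices worth stating explicitly:

* **Combination rule.** How the two criterion sets are combined is not
  uniquely determined by the phrase "a combination of the criteria"; we
  default to the **union** (unhealthy if either rule fires), the
  conservative reading, and expose an `intersection` mode
  (`classify_cohort(..., rule = "intersection")`) so the ambiguity is
  auditable rather than silent.
* **Percentile criteria.** The HOMA-IR and CRP thresholds are
  cohort-relative 90th percentiles computed with the **nearest-rank**
  method over the obese (BMI $\ge$ 30) stratum only. With distinct values,
  between $\lfloor 0.1 n \rfloor$ and $\lceil 0.1 n \rceil$ obese subjects
  meet each percentile criterion.
* **Boundaries.** BP, TAG and glucose thresholds are inclusive ($\ge$);
  waist is strictly greater; HDL is strictly below the sex cut-off. The
  HDL source criterion is printed without an inequality in the original
  table, so we adopt "< cut-off" as the complement of the healthy
  definition (HDL above the cut-off).
* **Missing data.** Subjects are complete-case filtered
  (`filter_complete()`) before classification, mirroring the study design;
  if a biomarker is nonetheless missing, its criterion contributes zero
  and the fact is implicit in the counts. HOMA-IR is
  insulin $\times$ glucose / 22.5, with insulin treated as an opaque unit
  (the source reports inconsistent insulin units; the percentile criterion
  is unit-invariant).

## Inheritance coding and per-SNP model choice

Each SNP is coded from its risk-allele copy number $r \in \{0, 1, 2\}$
under three inheritance models: codominant $(0, 1, 2)$, dominant
$(0, 2, 2)$ and recessive $(0, 0, 2)$. Dominant carriers are coded **2,
not 1** — this is how the score is defined and it fixes the oGRS scale at
0–2 per SNP; a conventional $(0,1,1)$ carrier coding would halve dominant
SNPs' contributions. For each SNP, the adjusted logistic model
`status ~ code + age + sex + education` is fitted under all three codings
and the model with the **lowest SNP-term Wald p-value** wins; ties go to
the higher Cox & Snell $R^2$ ($1 - \exp\{\tfrac{2}{n}(\ell_0 - \ell_1)\}$),
then to the fixed order codominant, dominant, recessive. p-value is
primary because the downstream optimization consumes exactly that
quantity. The codominant model is fitted as a single numeric trend term by
default (one code per genotype implies one term); a 2-df indicator coding
is available via `codominant_coding = "indicator"`, where the SNP p-value
is the 2-df likelihood-ratio test.

Risk alleles are oriented from the data: an adjusted additive-dosage fit
per SNP, taking the allele whose odds ratio exceeds 1
(`determine_risk_allele()`). Known literature risk alleles can be forced
by constructing codings directly with `inheritance_coding()`.
Monomorphic SNPs, codings without contrast, and non-converged fits
(separation heuristic: any slope $|\beta| > 15$) are dropped with a
logged reason.

## The greedy score optimization

Candidates are ranked by ascending single-SNP p-value (ties by higher
$R^2$, then lexicographic ID, so the ordering is deterministic). The
score starts empty; each candidate in turn is trial-added and the adjusted
model `status ~ oGRS + age + sex + education` refitted. The candidate is
**kept only if the score term's p-value strictly decreases** relative to
the best achieved so far; the first candidate is accepted unconditionally
(it defines the initial association), rejected candidates are removed
permanently, and there is no backtracking — a single successive-insertion
sweep. The full trial trajectory (one row per candidate, accepted or not)
is recorded in the result.

Two properties of this acceptance rule deserve emphasis. First, accepted
steps have strictly decreasing p-values by construction, so the procedure
terminates and is a pure function of the ranked list and the data.
Second, the rule is a *relative-improvement* gate with no significance
floor: on data with no true signal, candidates that correlate with the
outcome by chance still improve the in-sample p-value, so the procedure
will happily accumulate SNPs and overfit. This is inherent to the
published procedure, not an artifact of this implementation; it is why
the pipeline computes a split-half train/test AUC gap on every run (the
`overfit_guard` report section) and why a cross-validated AUC
(`cv_auc()`) is provided alongside the apparent one. Users should read
the selected-SNP count and apparent AUC as in-sample quantities.

Tertile risk groups cut the score at the nearest-rank 1/3 and 2/3
quantiles; subjects tied with a cut point all go to the lower group
(group sizes may therefore differ by the tie counts, and integer scores
with fewer than three distinct values are rejected).

## Discrimination and the minimal subset

AUC is the Mann–Whitney estimator
$P(\text{score}_\text{case} > \text{score}_\text{control}) + \tfrac12
P(\text{tie})$, computed from midranks; `roc_curve()` returns one point
per distinct threshold and its trapezoidal area equals the Mann–Whitney
value exactly. Paired AUC comparisons use **DeLong's** placement-value
(structural-component) covariance estimator; the source workflow names
only "a statistical comparison of the AUC curves", and DeLong's test is
the de facto standard behind that phrase, so it is the default, with a
stratified bootstrap (`bootstrap_auc_test()`) as a cross-check. The
minimal subset search asks for the smallest *prefix* of the selection
order whose score is not significantly worse than the full score
(comparison p above the Bonferroni-corrected threshold); prefixes — not
all subsets — because the question is about "the top-ranked SNPs", and
the full score compared with itself gives p = 1, guaranteeing
termination.

Multivariable panels (conventional risk factors: age, sex, education,
BMI; optionally plus a score) are turned into ROC scores via in-sample
fitted probabilities of an adjusted logistic model (`combined_score()`),
matching how such AUCs are usually reported; these are apparent AUCs and
optimistically biased, which is flagged wherever they appear.

## Survival, trend and interaction analyses

Exact MUO onset ages are unobservable in a cross-sectional survey, so the
Cox model uses **age at survey** as the time axis: unhealthy subjects are
events at their survey age, healthy subjects are right-censored at
theirs. This is the only reading under which "cumulative risk of MUO in
relation to age" is well defined for these data. Ages are integer-valued
and heavily tied, hence **Efron** tie handling. The default adjustment is
sex and education (age is the time axis and must not also be a
covariate); fitting is delegated to `survival::coxph`, and cumulative
risk curves per risk group are Kaplan–Meier complements.

Ordered-trend questions (outcome prevalence across risk groups, score
means across BMI strata) use the **Jonckheere–Terpstra** test: the sum of
pairwise Mann–Whitney counts of later over earlier groups, with a
tie-corrected normal approximation, or exhaustive permutation enumeration
when the pooled sample is small (n $\le$ 12). The Mann–Whitney U test
follows the same exact/approximate split. Non-normal biomarkers (screened
by Shapiro–Wilk) can be normalized by the rank-based two-step transform:
fractional midranks $r_i/(n+1)$ followed by standard-normal quantiles —
strictly rank-preserving.

Interaction models on a total population (all BMI strata) fit, per score,
the score alone and the score-by-BMI product term, adjusted for age, sex,
education, BMI and the score's main effect. Bonferroni thresholds are
always computed as $\alpha/m$ with an explicit $m$
(`bonferroni_threshold()`), never inferred silently; $m = 19$ at
$\alpha = 0.05$ gives the conventional two-significant-figure threshold
0.0026.

## What the synthetic cohort emulates

`generate_cohort()` composes four generators, every one a pure function
of the configuration and a named seed substream:

* **Genotypes** are Hardy–Weinberg draws — Binomial(2, q) copies of the
  risk allele at MAF q — independently per SNP. There is no linkage
  disequilibrium, population structure or genotyping error; the analysis
  treats SNPs marginally, so its operating characteristics do not depend
  on LD, but any conclusion about correlated panels is outside what the
  simulations can show.
* **Covariates**: age truncated-normal (default mean 52.6, SD 11, range
  20–80 — the status-weighted moments implied by the published group
  means), sex Bernoulli(0.5), education multinomial (0.29/0.61/0.10,
  the published cohort proportions).
* **Status** follows a centred logistic liability:
  $\text{logit}\,P(\text{MUO}) = \beta_0 + \sum_i \beta_i (G_i - E[G_i])
  + \gamma_a(\text{age}-\bar{\text{age}}) + \dots$ with 19 causal SNPs
  (of 67) of mixed inheritance modes, effect sizes front-loaded on four
  lead variants (log-OR 0.55–0.65, the scale of the strongest published
  single-SNP association, OR $\approx$ 1.9) and 0.25–0.42 for the rest.
  Centring keeps the marginal prevalence interpretable; because the
  logistic link is non-linear, the default intercept is **solved
  numerically** so that the marginal prevalence equals the target (0.796,
  the published MUO share of the obese sample) given the variance of the
  centred liability — without this correction the realized prevalence
  would sit several points below the intercept's nominal value. The
  default age effect (0.05 log-odds/year) reproduces the published
  ~9-year age gap between the status groups.
* **Biomarkers** are drawn conditional on status with group means set to
  the published group-conditional means. The source prints only means and
  95% CIs, so SDs are back-calculated as
  $\text{SD} = \text{half-width}\times\sqrt{n_\text{group}}/1.96$
  ($n$ = 81 healthy / 317 unhealthy) — the only dispersion information
  available. Right-skewed biomarkers (TAG, insulin, CRP) are log-normal
  with log-scale parameters chosen to match the arithmetic mean and SD
  (the workflow's own use of a normalizing transform implies skew);
  the rest are truncated normals. One printed interval (healthy HDL) has
  its lower bound equal to the mean — an evident typographical defect —
  so its SD uses the upper half-width only. Cross-biomarker correlation
  defaults to zero: the source gives no correlation structure, and this
  is a config-level assumption, not a claim about real data. Medication
  flags are Bernoulli at the published prevalences. For obese cohorts,
  BMI is truncated at 30 (the realized mean sits slightly above the
  nominal target as a consequence).

Two modes decouple the machinery under test: `direct_status` keeps the
liability label as the subject's status (isolating the score machinery
from classification noise), while `biomarker_driven` discards it and lets
the phenotype classifier decide from the simulated biomarkers — because
the real cohort's group means are truncated by the very criteria that
define the groups, classifier/label agreement is high but deliberately
imperfect (above 0.8 in the test suite's check at n = 4000).

Because the generator omits LD, biomarker correlation, truncation-induced
distribution shapes and any genotype–biomarker pathway other than the
status label, passing tests demonstrate that the *pipeline machinery* is
correct and well calibrated under its stated assumptions — not that the
published effect sizes would replicate in new human data.

## Numerical choices and degenerate inputs

* Logistic fits use IRLS (`stats::glm.fit`) with Wald inference
  ($\exp(\beta \pm 1.96\,\text{SE})$); separation is flagged when any
  slope exceeds 15 in absolute value, and flagged fits are excluded with
  a logged reason.
* The Hardy–Weinberg screen is a 1-df Pearson $\chi^2$ against
  expectations from the observed allele frequency; violating SNPs (at the
  Bonferroni-corrected level $\alpha/m$ over the panel) are excluded by
  default (`hwe_action = "flag"` to keep them). Monomorphic SNPs report
  $\chi^2 = 0$ and are flagged rather than tested.
* Tertile ties go to the lower group; all-tied scores are an error.
* DeLong with zero variance: identical scores give p = 1; zero variance
  with a non-zero AUC difference is an error.
* Exact rank-test enumeration switches on at pooled n $\le$ 12
  (multiset-combination recursion); beyond that, tie-corrected normal
  approximations.
* All randomness flows from one master seed through named substreams
  (`substream_seed()`), so a pipeline run is byte-reproducible while
  stages remain independently reproducible.

## Problem sizes used by the test suite

The suite exercises the pipeline at the development-sample scale
(n = 398, 67 SNPs) for selection behaviour (200 signal replicates plus
100 permuted-label replicates), n = 20 000 single-SNP cohorts for
parameter and inheritance-mode recovery (100 replicates per mode),
1000 null simulations for DeLong type-I calibration, and published-scale
group sizes (133/133/132 and 440/444/398) for trend-power checks. For the
BMI-strata trend power we simulate the published score gradient with the
within-group SD implied by the published unhealthy-group score CI
(SD $\approx$ 1.8); back-calculating SDs from the strata CIs with the
full BMI-group sizes would give dispersions (up to 8.2) that are
incompatible with a 19-SNP 0–2-coded score, because those CIs were
evidently computed on smaller status-by-BMI strata whose sizes are not
printed.

## A worked run

```{r run, eval = FALSE}
cfg <- simulation_config(n_subjects = 398, seed = 7)
report <- run_pipeline(pipeline_config(simulation = cfg, seed = 7))
print(report)
```

See the README for the printed output of this exact run and a walk-through
of the report sections.

## Known limitations

* The greedy acceptance rule overfits by construction on null data (see
  above); selected-SNP counts and apparent AUCs are in-sample quantities.
* Risk-allele orientation from the analysis sample uses the outcome, a
  mild form of double-dipping shared with the original workflow; supply
  literature alleles via `inheritance_coding()` to avoid it.
* The Cox "age at survey" outcome is a proxy for unobserved onset age;
  hazard ratios inherit that approximation.
* The synthetic generator's independence assumptions (no LD, no
  biomarker correlation) bound what simulation-based tests can
  demonstrate about real cohorts.
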