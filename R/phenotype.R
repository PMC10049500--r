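# Metabolic phenotype classification: combined Wildman/Meigs criteria,
# HOMA-IR, BMI strata, and complete-case filtering.
#
# Wildman criteria (flag when > 1 met): elevated BP (SBP >= 130 or
# DBP >= 85), BP medication, TAG >= 1.7 mM, low HDL (< 1.0 mM men /
# < 1.3 mM women), lipid medication, glucose >= 5.6 mM, diabetes
# medication, HOMA-IR >= cohort 90th percentile, CRP >= cohort 90th
# percentile (both percentiles over the obese stratum).
# Meigs criteria (flag when > 2 met): elevated BP, BP medication,
# TAG >= 1.7, low HDL, glucose >= 5.6, waist > 102 cm men / > 88 cm women
# (strictly greater).

#' Homeostasis model assessment of insulin resistance
#'
#' `HOMA-IR = fasting insulin x fasting glucose / 22.5`. Insulin is treated
#' as an opaque unit: the source data print mutually inconsistent insulin
#' units, so HOMA-IR values are comparable only within one unit convention;
#' the classifier only uses the cohort-relative 90th percentile, which is
#' unit-invariant.
#'
#' @param insulin Fasting insulin (cohort's unit convention).
#' @param glucose Fasting glucose (mM).
#' @return Numeric HOMA-IR; `NA` when either input is missing or zero.
#'   Negative inputs are an error.
#' @examples
#' compute_homa_ir(22.5, 1)  # 1
#' @export
compute_homa_ir <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE))
    stop("insulin and glucose must be positive")
  out <- insulin * glucose / 22.5
  out[!is.na(insulin) & insulin == 0] <- NA_real_
  out[!is.na(glucose) & glucose == 0] <- NA_real_
  out
}

#' Nearest-rank percentile
#'
#' The p-th percentile as the `ceiling(p * n)`-th order statistic, so that
#' at most `floor((1 - p) * n)` observations strictly exceed it.
#' @keywords internal
nearest_rank_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[max(1L, ceiling(p * length(x)))]
}

#' Cohort-relative classification thresholds
#'
#' Computes the 90th percentiles of HOMA-IR and CRP over the obese
#' (BMI >= 30) stratum of the supplied phenotype table, the reference
#' stratum the Wildman percentile criteria are defined on.
#'
#' @param phenotypes Phenotype data frame (see [generate_cohort()] for the
#'   column convention).
#' @return List with `homa_p90`, `crp_p90`, `n_obese`.
#' @export
cohort_thresholds <- function(phenotypes) {
  obese <- phenotypes[!is.na(phenotypes$bmi) & phenotypes$bmi >= 30, ]
  if (!nrow(obese)) stop("no obese (BMI >= 30) subjects to compute thresholds")
  homa <- compute_homa_ir(obese$insulin, obese$glucose)
  list(homa_p90 = nearest_rank_quantile(homa, 0.9),
       crp_p90 = nearest_rank_quantile(obese$crp, 0.9),
       n_obese = nrow(obese))
}

## Shared criterion evaluations; missing values count 0 and are tallied as
## unevaluated, mirroring a complete-case design upstream.
crit <- function(x) ifelse(is.na(x), FALSE, x)

base_criteria <- function(ph) {
  if (any(!is.na(ph$hdl) & is.na(ph$sex)))
    stop("sex is required to evaluate the HDL criterion")
  hdl_cut <- ifelse(ph$sex == "male", 1.0, 1.3)
  list(bp = crit(ph$sbp >= 130) | crit(ph$dbp >= 85),
       bp_meds = crit(ph$on_bp_meds),
       tag = crit(ph$tag >= 1.7),
       hdl = crit(ph$hdl < hdl_cut),
       glucose = crit(ph$glucose >= 5.6))
}

#' Wildman criterion count
#'
#' @param phenotypes Phenotype data frame.
#' @param homa_p90,crp_p90 Cohort-relative 90th-percentile thresholds from
#'   [cohort_thresholds()].
#' @return Data frame with per-subject `count` (0-9) and `flag`
#'   (`count > 1`).
#' @export
classify_wildman <- function(phenotypes, homa_p90, crp_p90) {
  b <- base_criteria(phenotypes)
  homa <- compute_homa_ir(phenotypes$insulin, phenotypes$glucose)
  count <- b$bp + b$bp_meds + b$tag + b$hdl +
    crit(phenotypes$on_lipid_meds) + b$glucose +
    crit(phenotypes$on_diabetes_meds) +
    crit(homa >= homa_p90) + crit(phenotypes$crp >= crp_p90)
  data.frame(count = as.integer(count), flag = count > 1L)
}

#' Meigs criterion count
#'
#' @param phenotypes Phenotype data frame.
#' @return Data frame with per-subject `count` (0-6) and `flag`
#'   (`count > 2`). The waist criterion is strictly greater than the
#'   sex-specific cut-off (102 cm men / 88 cm women).
#' @export
classify_meigs <- function(phenotypes) {
  b <- base_criteria(phenotypes)
  wc_cut <- ifelse(phenotypes$sex == "male", 102, 88)
  count <- b$bp + b$bp_meds + b$tag + b$hdl + b$glucose +
    crit(phenotypes$waist > wc_cut)
  data.frame(count = as.integer(count), flag = count > 2L)
}

#' Classify metabolic status by combined Wildman/Meigs criteria
#'
#' A subject is metabolically unhealthy when the Wildman rule (> 1
#' criterion) or the Meigs rule (> 2 criteria) fires (union rule, the
#' default); an intersection mode requiring both is available for
#' sensitivity analysis.
#'
#' @param phenotypes Phenotype data frame.
#' @param thresholds List from [cohort_thresholds()].
#' @param rule `"union"` (either rule fires) or `"intersection"` (both).
#' @return Data frame with `status` (`"MUO"`/`"MHO"`), `wildman_count`,
#'   `meigs_count`, `rule_fired` (`"wildman"`, `"meigs"`, `"both"`,
#'   `"neither"`).
#' @export
classify_cohort <- function(phenotypes, thresholds = cohort_thresholds(phenotypes),
                            rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  w <- classify_wildman(phenotypes, thresholds$homa_p90, thresholds$crp_p90)
  m <- classify_meigs(phenotypes)
  fired <- ifelse(w$flag & m$flag, "both",
                  ifelse(w$flag, "wildman",
                         ifelse(m$flag, "meigs", "neither")))
  unhealthy <- if (rule == "union") w$flag | m$flag else w$flag & m$flag
  data.frame(status = ifelse(unhealthy, "MUO", "MHO"),
             wildman_count = w$count, meigs_count = m$count,
             rule_fired = fired, stringsAsFactors = FALSE)
}

#' BMI stratum assignment
#'
#' Half-open intervals: normal `[0, 25)`, overweight `[25, 30)`, obese
#' `[30, Inf)`.
#'
#' @param bmi Numeric BMI (kg/m^2); must lie in (10, 100).
#' @return Ordered factor with levels normal < overweight < obese.
#' @export
assign_bmi_group <- function(bmi) {
  if (anyNA(bmi)) stop("bmi must not be missing")
  if (any(bmi <= 10 | bmi >= 100)) stop("bmi outside sanity bounds (10, 100)")
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"), ordered_result = TRUE)
}

#' Complete-case filter
#'
#' Retains subjects with all required phenotype fields present and no
#' missing genotype across the active SNP panel, logging each exclusion
#' with its reason.
#'
#' @param cohort A `cohort` object.
#' @param required_fields Phenotype columns that must be non-missing.
#' @return List with the filtered `cohort` and an `exclusions` data frame
#'   (`subject_id`, `reason`).
#' @export
filter_complete <- function(cohort,
                            required_fields = c("age", "sex", "education",
                                                "bmi", "waist", "sbp", "dbp",
                                                "tag", "hdl", "glucose",
                                                "insulin", "crp")) {
  ph <- cohort$phenotypes
  missing_pheno <- required_fields[!required_fields %in% names(ph)]
  if (length(missing_pheno))
    stop("phenotype table lacks fields: ",
         paste(missing_pheno, collapse = ", "))
  bad_ph <- rowSums(is.na(ph[, required_fields, drop = FALSE])) > 0
  bad_gt <- rowSums(is.na(cohort$genotypes$geno)) > 0
  reasons <- character(0); ids <- character(0)
  if (any(bad_ph)) {
    ids <- c(ids, ph$subject_id[bad_ph])
    reasons <- c(reasons, rep("incomplete phenotype", sum(bad_ph)))
  }
  if (any(bad_gt & !bad_ph)) {
    sel <- bad_gt & !bad_ph
    ids <- c(ids, ph$subject_id[sel])
    reasons <- c(reasons, rep("incomplete genotype", sum(sel)))
  }
  keep <- !(bad_ph | bad_gt)
  if (!any(keep)) stop("complete-case filter removed every subject")
  out <- cohort
  out$phenotypes <- ph[keep, , drop = FALSE]
  out$genotypes$geno <- cohort$genotypes$geno[keep, , drop = FALSE]
  out$genotypes$subject_ids <- cohort$genotypes$subject_ids[keep]
  if (!is.null(out$truth)) {
    out$truth$latent_prob <- cohort$truth$latent_prob[keep]
    out$truth$status <- cohort$truth$status[keep]
  }
  list(cohort = out,
       exclusions = data.frame(subject_id = ids, reason = reasons,
                               stringsAsFactors = FALSE))
}
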