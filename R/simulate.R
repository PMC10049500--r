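# Synthetic cohort generator. Emulates the statistical structure the oGRS
# analysis assumes: Hardy-Weinberg genotypes at configurable MAFs,
# covariates, a logistic liability for metabolically unhealthy status with
# mixed-inheritance causal SNPs, and biomarkers calibrated to published
# group-conditional means.

#' Default group-conditional biomarker targets
#'
#' Means are the published group means for metabolically healthy (MHO,
#' n = 81) and unhealthy (MUO, n = 317) obese subjects; standard deviations
#' are back-calculated from the 95% confidence intervals of those means as
#' `SD = half_width * sqrt(n) / 1.96`, the only dispersion information the
#' source table provides. Right-skewed biomarkers (TAG, insulin, CRP) are
#' simulated log-normally with the log-scale parameters chosen so the
#' arithmetic mean and SD match the targets; the rest are normal truncated
#' to positive values. The MHO HDL interval is printed with its lower bound
#' equal to the mean (a typographical defect), so its SD uses the upper
#' half-width only.
#'
#' @return A data frame with columns `biomarker`, `status`, `mean`, `sd`,
#'   `dist` (`"normal"` or `"lognormal"`).
#' @export
default_biomarker_targets <- function() {
  n_mho <- 81; n_muo <- 317
  row <- function(bm, status, mean, lo, hi, dist = "normal", hw = NULL) {
    n <- if (status == "MHO") n_mho else n_muo
    hw <- hw %||% ((hi - lo) / 2)
    data.frame(biomarker = bm, status = status, mean = mean,
               sd = hw * sqrt(n) / 1.96, dist = dist,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("bmi",     "MHO", 33.1,  32.4,  33.8),
    row("bmi",     "MUO", 34.5,  34.1,  35.0),
    row("waist",   "MHO", 106.9, 104.5, 109.2),
    row("waist",   "MUO", 112.9, 111.5, 114.2),
    row("sbp",     "MHO", 127.3, 123.9, 130.7),
    row("sbp",     "MUO", 141.0, 139.2, 142.8),
    row("dbp",     "MHO", 80.7,  78.9,  82.5),
    row("dbp",     "MUO", 85.0,  84.0,  86.1),
    row("tag",     "MHO", 1.20,  1.09,  1.30,  "lognormal"),
    row("tag",     "MUO", 2.21,  2.02,  2.39,  "lognormal"),
    row("hdl",     "MHO", 1.45,  NA,    NA,    hw = 0.07),
    row("hdl",     "MUO", 1.20,  1.17,  1.24),
    row("glucose", "MHO", 4.33,  4.16,  4.51),
    row("glucose", "MUO", 5.56,  5.33,  5.79),
    row("insulin", "MHO", 186.57, 165.36, 207.79, "lognormal"),
    row("insulin", "MUO", 278.59, 256.62, 300.57, "lognormal"),
    row("crp",     "MHO", 28.86, 23.66, 34.06, "lognormal"),
    row("crp",     "MUO", 45.52, 40.75, 50.30, "lognormal")
  )
}

#' Default medication-use prevalences by metabolic status
#' @return Data frame with columns `flag`, `status`, `prevalence`.
#' @export
default_medication_targets <- function() {
  data.frame(
    flag = rep(c("on_bp_meds", "on_diabetes_meds", "on_lipid_meds"), each = 2),
    status = rep(c("MHO", "MUO"), 3),
    prevalence = c(0.000, 0.754, 0.000, 0.161, 0.062, 0.315),
    stringsAsFactors = FALSE
  )
}

#' Standard deviation of the centred liability terms
#'
#' Under Hardy-Weinberg genotypes and the default covariate distributions,
#' the causal-SNP and covariate contributions to the liability have a
#' computable variance; this is used to calibrate the baseline logit so
#' the marginal prevalence hits its target despite the non-linearity of
#' the logistic link.
#' @keywords internal
liability_sd <- function(panel, covariate_effects, age_sd,
                         education_probs) {
  v <- 0
  for (j in which(panel$causal_flag)) {
    q <- panel$maf[j]
    vg <- switch(panel$true_model[j],
                 codominant = 2 * q * (1 - q),
                 dominant   = {p2 <- 1 - (1 - q)^2; 4 * p2 * (1 - p2)},
                 recessive  = {p2 <- q^2; 4 * p2 * (1 - p2)})
    v <- v + panel$true_log_or[j]^2 * vg
  }
  e <- covariate_effects
  v <- v + (e$age %||% 0)^2 * age_sd^2 + (e$sex %||% 0)^2 * 0.25
  lv <- seq_along(education_probs)
  v <- v + (e$education %||% 0)^2 *
    (sum(lv^2 * education_probs) - sum(lv * education_probs)^2)
  sqrt(v)
}

## numerically solve E[plogis(mu + sigma Z)] = target for mu,
## with Z standard normal (the liability sum is close to normal)
calibrate_baseline_logit <- function(target, sigma) {
  z <- stats::qnorm(seq(0.0005, 0.9995, by = 0.001))
  stats::uniroot(function(mu) mean(stats::plogis(mu + sigma * z)) - target,
                 interval = c(-20, 20), tol = 1e-10)$root
}

#' Build a simulation configuration
#'
#' @param n_subjects Cohort size (>= 2). Default 398, the size of the obese
#'   stratum the score is developed on.
#' @param panel A [snp_panel()]; defaults to [default_snp_panel()].
#' @param baseline_logit Intercept of the liability model. All liability
#'   terms are centred, and the default (`NULL`) solves for the intercept
#'   that gives a marginal prevalence of `target_prevalence` given the
#'   variance of the centred terms, reproducing the ~80% unhealthy
#'   prevalence of the obese study sample.
#' @param target_prevalence Marginal unhealthy prevalence the default
#'   intercept is calibrated to (ignored when `baseline_logit` is given).
#' @param covariate_effects Named list of log-odds per unit for `age`
#'   (centred at the cohort mean), `sex` (male = 1) and `education`
#'   (ordinal 1-3, centred at 2). The default age effect (0.05/year)
#'   reproduces the ~9-year age gap between status groups.
#' @param biomarker_targets See [default_biomarker_targets()].
#' @param medication_targets See [default_medication_targets()].
#' @param mode `"direct_status"` keeps the simulated liability label as the
#'   subject's status; `"biomarker_driven"` discards it and lets the
#'   phenotype classifier decide from the simulated biomarkers.
#' @param population `"obese"` truncates BMI at 30 (development stratum);
#'   `"total"` draws BMI from a three-group mixture matching the published
#'   normal/overweight/obese split (440/444/398).
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated).
#' @param education_probs Probabilities of the three education levels.
#' @param seed Master seed; every generator derives a named substream
#'   from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 398,
                              panel = default_snp_panel(),
                              baseline_logit = NULL,
                              target_prevalence = 0.796,
                              covariate_effects = list(age = 0.05, sex = 0,
                                                       education = 0),
                              biomarker_targets = default_biomarker_targets(),
                              medication_targets = default_medication_targets(),
                              mode = c("direct_status", "biomarker_driven"),
                              population = c("obese", "total"),
                              age_mean = 52.6, age_sd = 11,
                              age_range = c(20, 80),
                              education_probs = c(0.29, 0.61, 0.10),
                              seed = 1L) {
  mode <- match.arg(mode)
  population <- match.arg(population)
  stopifnot(n_subjects >= 2, inherits(panel, "snp_panel"),
            all(biomarker_targets$sd > 0),
            abs(sum(education_probs) - 1) < 1e-8)
  if (is.null(baseline_logit)) {
    stopifnot(target_prevalence > 0, target_prevalence < 1)
    baseline_logit <- calibrate_baseline_logit(
      target_prevalence,
      liability_sd(panel, covariate_effects, age_sd, education_probs))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), panel = panel,
    baseline_logit = baseline_logit, covariate_effects = covariate_effects,
    biomarker_targets = biomarker_targets,
    medication_targets = medication_targets,
    mode = mode, population = population,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    education_probs = education_probs, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate Hardy-Weinberg genotypes for a SNP panel
#'
#' Each SNP's genotypes are drawn independently with probabilities
#' `(1-q)^2, 2q(1-q), q^2` for 0/1/2 copies of `allele_b` at MAF `q`
#' (a Binomial(2, q) dosage), so generated panels conform to
#' Hardy-Weinberg equilibrium by construction.
#'
#' @param panel A [snp_panel()].
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [genotype_matrix()] of unphased allele pairs such as `"A/G"`.
#' @export
generate_genotypes <- function(panel, n, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"), nrow(panel) >= 1)
  if (!is.numeric(n) || n < 2) stop("n must be a positive integer >= 2")
  set.seed(substream_seed(seed, "genotypes"))
  n <- as.integer(n)
  geno <- matrix(NA_character_, nrow = n, ncol = nrow(panel),
                 dimnames = list(sprintf("S%04d", seq_len(n)), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    dose <- stats::rbinom(n, 2L, panel$maf[j])
    a <- panel$allele_a[j]; b <- panel$allele_b[j]
    geno[, j] <- c(paste(a, a, sep = "/"),
                   paste(a, b, sep = "/"),
                   paste(b, b, sep = "/"))[dose + 1L]
  }
  genotype_matrix(geno, panel[, c("snp_id", "allele_a", "allele_b")])
}

#' Generate covariates (age, sex, education)
#'
#' Age is truncated normal (defaults spanning roughly 20-80 years), sex is
#' Bernoulli(0.5) coded `"male"`/`"female"`, and education is a three-level
#' ordinal drawn with the published cohort proportions (~0.29 primary,
#' 0.61 secondary/vocational, 0.10 college/university).
#'
#' @inheritParams generate_genotypes
#' @param config A [simulation_config()] supplying the distributions.
#' @return Data frame with `subject_id`, `age`, `sex`, `education`.
#' @export
generate_covariates <- function(n, seed = 1L, config = simulation_config()) {
  if (!is.numeric(n) || n < 2) stop("n must be a positive integer >= 2")
  set.seed(substream_seed(seed, "covariates"))
  n <- as.integer(n)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  lo <- config$age_range[1]; hi <- config$age_range[2]
  while (any(bad <- age < lo | age > hi))
    age[bad] <- stats::rnorm(sum(bad), config$age_mean, config$age_sd)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = round(age),
    sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
    education = sample.int(3L, n, replace = TRUE,
                           prob = config$education_probs),
    stringsAsFactors = FALSE
  )
}

## expected model code under HWE for centring the liability
expected_code <- function(model, q) {
  switch(model,
         codominant = 2 * q,
         dominant   = 2 * (1 - (1 - q)^2),
         recessive  = 2 * q^2,
         stop("unknown model: ", model))
}

#' Simulate metabolically unhealthy status from a logistic liability
#'
#' The liability is `baseline_logit + sum_causal beta_i (G_i - E[G_i]) +
#' covariate terms`, where `G_i` codes the SNP under its true inheritance
#' model with `allele_b` as risk allele and `E[G_i]` is its
#' Hardy-Weinberg expectation. Centring keeps the marginal prevalence at
#' approximately `plogis(baseline_logit)` whatever the effect sizes.
#'
#' @param genotypes A [genotype_matrix()].
#' @param covariates Data frame from [generate_covariates()].
#' @param config A [simulation_config()].
#' @return Data frame with `subject_id`, `latent_prob`, `status`
#'   (`"MUO"`/`"MHO"`).
#' @export
generate_status <- function(genotypes, covariates, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  n <- length(genotypes$subject_ids)
  if (n != nrow(covariates)) stop("genotype/covariate row counts differ")
  set.seed(substream_seed(config$seed, "status"))
  panel <- config$panel
  lp <- rep(config$baseline_logit, n)
  for (j in which(panel$causal_flag)) {
    codes <- code_genotype(genotypes$geno[, panel$snp_id[j]],
                           risk_allele = panel$allele_b[j],
                           model = panel$true_model[j],
                           alleles = c(panel$allele_a[j], panel$allele_b[j]))
    lp <- lp + panel$true_log_or[j] *
      (codes - expected_code(panel$true_model[j], panel$maf[j]))
  }
  eff <- config$covariate_effects
  lp <- lp + (eff$age %||% 0) * (covariates$age - mean(covariates$age)) +
    (eff$sex %||% 0) * (covariates$sex == "male") +
    (eff$education %||% 0) * (covariates$education - 2)
  prob <- stats::plogis(lp)
  data.frame(subject_id = covariates$subject_id,
             latent_prob = prob,
             status = ifelse(stats::runif(n) < prob, "MUO", "MHO"),
             stringsAsFactors = FALSE)
}

#' Simulate biomarkers and medication flags conditional on status
#'
#' @param status Character vector of `"MHO"`/`"MUO"` labels.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Data frame of biomarker columns plus logical medication flags.
#' @export
generate_biomarkers <- function(status, config, seed = 1L) {
  stopifnot(all(status %in% c("MHO", "MUO")))
  targets <- config$biomarker_targets
  if (any(targets$sd <= 0)) stop("biomarker SDs must be positive")
  for (s in c("MHO", "MUO"))
    if (!all(unique(targets$biomarker) %in%
             targets$biomarker[targets$status == s]))
      stop("biomarker_targets must cover both statuses")
  set.seed(substream_seed(seed, "biomarkers"))
  n <- length(status)
  out <- data.frame(row.names = seq_len(n))
  for (bm in unique(targets$biomarker)) {
    x <- numeric(n)
    for (s in c("MHO", "MUO")) {
      idx <- which(status == s)
      if (!length(idx)) next
      t <- targets[targets$biomarker == bm & targets$status == s, ]
      if (t$dist == "lognormal") {
        sigma2 <- log(1 + (t$sd / t$mean)^2)
        x[idx] <- stats::rlnorm(length(idx), log(t$mean) - sigma2 / 2,
                                sqrt(sigma2))
      } else {
        v <- stats::rnorm(length(idx), t$mean, t$sd)
        lo <- if (bm == "bmi" && config$population == "obese") 30 else 0.01
        while (any(bad <- v < lo))
          v[bad] <- stats::rnorm(sum(bad), t$mean, t$sd)
        x[idx] <- v
      }
    }
    out[[bm]] <- x
  }
  meds <- config$medication_targets
  for (fl in unique(meds$flag)) {
    p <- stats::setNames(meds$prevalence[meds$flag == fl],
                         meds$status[meds$flag == fl])
    out[[fl]] <- stats::runif(n) < p[status]
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Composes the genotype, covariate, status and biomarker generators. In
#' `direct_status` mode the liability label is the subject's metabolic
#' status; in `biomarker_driven` mode the status is re-derived by the
#' phenotype classifier ([classify_cohort()]) from the simulated
#' biomarkers, so classification noise propagates as it would in real data.
#' The generative truth (latent probability and simulated label) is kept in
#' `$truth` for recovery tests.
#'
#' @param config A [simulation_config()].
#' @return A `cohort` object: list with `phenotypes` (data frame),
#'   `genotypes` ([genotype_matrix()]), `panel`, and `truth`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  genotypes <- generate_genotypes(config$panel, n, config$seed)
  covariates <- generate_covariates(n, config$seed, config)
  truth <- generate_status(genotypes, covariates, config)
  biomarkers <- generate_biomarkers(truth$status, config, config$seed)
  if (config$population == "total") {
    ## BMI mixture over the published normal/overweight/obese split
    set.seed(substream_seed(config$seed, "bmi_total"))
    grp <- sample.int(3L, n, replace = TRUE,
                      prob = c(440, 444, 398) / 1282)
    bmi <- numeric(n)
    pars <- list(c(22.5, 1.8, 16, 24.99), c(27.4, 1.4, 25, 29.99))
    for (g in 1:2) {
      idx <- which(grp == g); p <- pars[[g]]
      v <- stats::rnorm(length(idx), p[1], p[2])
      while (any(bad <- v < p[3] | v > p[4]))
        v[bad] <- stats::rnorm(sum(bad), p[1], p[2])
      bmi[idx] <- v
    }
    keep <- grp == 3L  # obese keep their status-conditional BMI
    bmi[keep] <- biomarkers$bmi[keep]
    biomarkers$bmi <- bmi
  }
  phenotypes <- cbind(covariates, biomarkers)
  phenotypes$status <- truth$status
  cohort <- structure(list(phenotypes = phenotypes, genotypes = genotypes,
                           panel = config$panel,
                           truth = list(latent_prob = truth$latent_prob,
                                        status = truth$status,
                                        mode = config$mode)),
                      class = "cohort")
  if (config$mode == "biomarker_driven") {
    thr <- cohort_thresholds(cohort$phenotypes)
    cls <- classify_cohort(cohort$phenotypes, thr)
    cohort$phenotypes$status <- cls$status
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d SNPs (%s)\n",
              nrow(x$phenotypes), length(x$genotypes$snp_ids),
              x$truth$mode))
  if ("status" %in% names(x$phenotypes))
    print(table(x$phenotypes$status))
  invisible(x)
}
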