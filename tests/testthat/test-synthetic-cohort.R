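# The generator must produce Hardy-Weinberg genotypes, calibrated
# covariates and biomarkers, and a liability model whose parameters are
# recoverable -- otherwise nothing downstream is interpretable.

test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  panel <- snp_panel("rs1", "G1", "A", "G", maf = 0.5)
  gm <- generate_genotypes(panel, 10000, seed = 1)
  counts <- table(factor(gm$geno[, 1], levels = c("A/A", "A/G", "G/G")))
  expected <- c(0.25, 0.5, 0.25)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(counts / 10000 - expected) < 3 * se))

  gm2 <- generate_genotypes(panel, 10000, seed = 1)
  expect_identical(gm$geno, gm2$geno)

  panel2 <- snp_panel("rs2", "G2", "C", "T", maf = 0.2)
  gm3 <- generate_genotypes(panel2, 50000, seed = 2)
  dose <- code_genotype(gm3$geno[, 1], "T", "codominant")
  se_dose <- sqrt(2 * 0.2 * 0.8 / 50000)
  expect_lt(abs(mean(dose) - 0.4), 3 * se_dose)
})

test_that("invalid generator inputs are rejected", {
  panel <- snp_panel("rs1", "G1", "A", "G", maf = 0.3)
  expect_error(generate_genotypes(panel, 0), "positive")
  expect_error(snp_panel("rs1", "G1", "A", "G", maf = 0.6), "maf")
  expect_error(snp_panel("rs1", "G1", "A", "A", maf = 0.3), "differ")
  expect_error(generate_covariates(1), "positive")
})

test_that("covariates match their target distributions", {
  cov <- generate_covariates(100000, seed = 4)
  expect_lt(abs(mean(cov$sex == "male") - 0.5), 3 * sqrt(0.25 / 1e5))
  p3 <- mean(cov$education == 3)
  expect_lt(abs(p3 - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))
  expect_true(all(cov$age >= 20 & cov$age <= 80))
  expect_identical(cov, generate_covariates(100000, seed = 4))
})

test_that("status generator hits its marginal prevalence", {
  panel <- snp_panel("rs1", "G1", "A", "G", maf = 0.3)
  null_effects <- list(age = 0, sex = 0, education = 0)
  # neutral liability -> 50% prevalence
  cfg0 <- simulation_config(n_subjects = 20000, panel = panel,
                            baseline_logit = 0,
                            covariate_effects = null_effects, seed = 5)
  st0 <- generate_status(generate_genotypes(panel, 20000, 5),
                         generate_covariates(20000, 5, cfg0), cfg0)
  expect_lt(abs(mean(st0$status == "MUO") - 0.5), 3 * sqrt(0.25 / 20000))

  # baseline logit +1.386 alone -> prevalence ~0.80, the study's MUO rate
  cfg1 <- simulation_config(n_subjects = 50000, panel = panel,
                            baseline_logit = 1.386,
                            covariate_effects = null_effects, seed = 6)
  st1 <- generate_status(generate_genotypes(panel, 50000, 6),
                         generate_covariates(50000, 6, cfg1), cfg1)
  p <- plogis(1.386)
  expect_lt(abs(mean(st1$status == "MUO") - p),
            3 * sqrt(p * (1 - p) / 50000))
})

test_that("a dominant ln(2) effect is recovered by logistic refit", {
  panel <- single_snp_panel("dominant", log(2), maf = 0.3)
  cfg <- simulation_config(n_subjects = 50000, panel = panel,
                           baseline_logit = 0,
                           covariate_effects = list(age = 0, sex = 0,
                                                    education = 0),
                           seed = 7)
  gm <- generate_genotypes(panel, 50000, 7)
  st <- generate_status(gm, generate_covariates(50000, 7, cfg), cfg)
  codes <- code_genotype(gm$geno[, 1], "G", "dominant")
  fit <- fit_logistic(as.integer(st$status == "MUO"),
                      cbind(snp = codes))
  expect_gt(fit$or["snp"], 1.8)
  expect_lt(fit$or["snp"], 2.2)
})

test_that("biomarker means match the published group targets", {
  cfg <- simulation_config(seed = 8)
  bio_muo <- generate_biomarkers(rep("MUO", 20000), cfg, seed = 8)
  tgt <- cfg$biomarker_targets
  t_tag <- tgt[tgt$biomarker == "tag" & tgt$status == "MUO", ]
  expect_lt(abs(mean(bio_muo$tag) - t_tag$mean),
            3 * t_tag$sd / sqrt(20000))
  bio_mho <- generate_biomarkers(rep("MHO", 20000), cfg, seed = 9)
  t_sbp <- tgt[tgt$biomarker == "sbp" & tgt$status == "MHO", ]
  expect_lt(abs(mean(bio_mho$sbp) - t_sbp$mean),
            3 * t_sbp$sd / sqrt(20000))
  # medication flags follow their status-conditional prevalences
  expect_equal(mean(bio_mho$on_bp_meds), 0)
  expect_lt(abs(mean(bio_muo$on_bp_meds) - 0.754),
            3 * sqrt(0.754 * 0.246 / 20000))
})

test_that("degenerate biomarker dispersion is rejected", {
  cfg <- simulation_config(seed = 1)
  cfg$biomarker_targets$sd[1] <- 0
  expect_error(generate_biomarkers(rep("MUO", 10), cfg, 1), "positive")
  expect_error(simulation_config(
    biomarker_targets = transform(default_biomarker_targets(),
                                  sd = 0)), "sd")
})

test_that("cohorts are reproducible and truth is wired through", {
  cfg <- simulation_config(n_subjects = 300, seed = 10)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_identical(co1$genotypes$geno, co2$genotypes$geno)
  # direct mode: status column is the generative label
  expect_identical(co1$phenotypes$status, co1$truth$status)
  # written files are byte-identical across runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_phenotype_csv(co1$phenotypes, f1)
  write_phenotype_csv(co2$phenotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("biomarker-driven classification agrees with the generating label", {
  cfg <- simulation_config(n_subjects = 4000, mode = "biomarker_driven",
                           seed = 2)
  co <- generate_cohort(cfg)
  agreement <- mean(co$phenotypes$status == co$truth$status)
  expect_gt(agreement, 0.8)
})

test_that("generated SNPs pass the HWE screen at the nominal rate", {
  # ~5% of null HWE tests should reject at alpha = 0.05
  panel <- snp_panel("rs1", "G1", "A", "G", maf = 0.3)
  rej <- vapply(1:400, function(s) {
    gm <- generate_genotypes(panel, 500, seed = s)
    hwe_test(genotype_counts(gm, "rs1"))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})
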