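# End-to-end orchestration: filter -> classify -> HWE screen -> code ->
# model selection -> rank -> greedy optimization -> risk groups -> ROC
# panel -> minimal subset -> survival/trend/interaction analyses ->
# serialized report.

#' Adjustment covariate matrix (age, sex, education)
#'
#' The standard adjustment set of every regression in the workflow:
#' age in years, sex as male = 1, education as the ordinal 1-3 level.
#'
#' @param phenotypes Phenotype data frame.
#' @return Numeric matrix with columns `age`, `sex`, `education`.
#' @export
adjustment_matrix <- function(phenotypes) {
  cbind(age = as.numeric(phenotypes$age),
        sex = as.numeric(phenotypes$sex == "male"),
        education = as.numeric(phenotypes$education))
}

#' Per-group outcome prevalence with exact CIs and trend test
#'
#' Prevalence of the binary outcome per ordered risk group with
#' Clopper-Pearson 95% intervals, plus the Jonckheere-Terpstra trend
#' p-value of the outcome across the group ordering.
#'
#' @param outcome 0/1 vector (1 = metabolically unhealthy).
#' @param groups Ordered factor partitioning the subjects (e.g. from
#'   [assign_risk_groups()]).
#' @return List with `table` (group, n, n_outcome, prevalence_pct, CI) and
#'   `trend_p`.
#' @export
prevalence_by_risk_group <- function(outcome, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty risk group")
  tab <- do.call(rbind, lapply(levels(groups), function(g) {
    n <- sum(groups == g); k <- sum(outcome[groups == g])
    ci <- stats::binom.test(k, n)$conf.int
    data.frame(group = g, n = n, n_outcome = k,
               prevalence_pct = 100 * k / n,
               ci_lower_pct = 100 * ci[1], ci_upper_pct = 100 * ci[2],
               stringsAsFactors = FALSE)
  }))
  trend_p <- if (nlevels(droplevels(groups)) >= 2)
    jonckheere_terpstra(outcome, groups, alternative = "increasing")$p
  else NA_real_
  list(table = tab, trend_p = trend_p)
}

#' Build a pipeline configuration
#'
#' Exactly one input source must be active: a [simulation_config()] or a
#' pair of genotype/phenotype CSV paths.
#'
#' @param simulation Optional [simulation_config()].
#' @param genotype_csv,phenotype_csv Optional input CSV paths (see
#'   [read_genotype_csv()], [read_phenotype_csv()]).
#' @param rule Classification combination rule (`"union"` or
#'   `"intersection"`).
#' @param hwe_alpha Family-wise level of the Hardy-Weinberg screen (the
#'   per-SNP threshold is `hwe_alpha / n_snps`).
#' @param hwe_action `"exclude"` drops violating SNPs, `"flag"` only
#'   reports them.
#' @param alpha Nominal significance level used to derive Bonferroni
#'   thresholds downstream.
#' @param outdir Optional output directory for the serialized report.
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, genotype_csv = NULL,
                            phenotype_csv = NULL,
                            rule = c("union", "intersection"),
                            hwe_alpha = 0.05,
                            hwe_action = c("exclude", "flag"),
                            alpha = 0.05, outdir = NULL, seed = 1L) {
  rule <- match.arg(rule)
  hwe_action <- match.arg(hwe_action)
  stopifnot(alpha > 0, alpha < 1)
  have_sim <- !is.null(simulation)
  have_files <- !is.null(genotype_csv) && !is.null(phenotype_csv)
  if (have_sim == have_files)
    stop("exactly one of {simulation config, input CSV paths} must be given")
  structure(list(simulation = simulation, genotype_csv = genotype_csv,
                 phenotype_csv = phenotype_csv, rule = rule,
                 hwe_alpha = hwe_alpha, hwe_action = hwe_action,
                 alpha = alpha, outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full oGRS analysis pipeline
#'
#' Executes every stage of the workflow on a simulated or file-based
#' cohort and returns a structured report. Identical configuration and
#' seed give an identical report.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list; see the package vignette for the section
#'   layout. When `config$outdir` is set, the report is also written as
#'   `report.json` plus TSV side tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- stage("input", {
    if (!is.null(config$simulation)) generate_cohort(config$simulation)
    else structure(list(
      phenotypes = read_phenotype_csv(config$phenotype_csv),
      genotypes = read_genotype_csv(config$genotype_csv),
      panel = NULL, truth = NULL), class = "cohort")
  })

  filt <- stage("filter", filter_complete(cohort))
  cohort <- filt$cohort
  ph <- cohort$phenotypes

  cls <- stage("classify", {
    thr <- cohort_thresholds(ph)
    cl <- classify_cohort(ph, thr, rule = config$rule)
    if (length(unique(cl$status)) < 2L)
      stop("classification produced a single status class (",
           cl$status[1], " only); downstream modelling is impossible")
    list(thresholds = thr, classes = cl)
  })
  outcome <- as.integer(cls$classes$status == "MUO")
  covars <- adjustment_matrix(ph)

  hwe <- stage("hwe_screen", {
    res <- do.call(rbind, lapply(cohort$genotypes$snp_ids, function(id) {
      h <- hwe_test(genotype_counts(cohort$genotypes, id))
      data.frame(snp_id = id, chi2 = h$chi2, p = h$p,
                 monomorphic = h$monomorphic, stringsAsFactors = FALSE)
    }))
    thr_hwe <- config$hwe_alpha / nrow(res)
    res$violates <- res$p < thr_hwe
    res
  })
  active <- if (config$hwe_action == "exclude")
    hwe$snp_id[!hwe$violates & !hwe$monomorphic] else
      hwe$snp_id[!hwe$monomorphic]

  sel <- stage("model_selection",
               select_models(cohort$genotypes, outcome, covars,
                             snp_ids = active))
  if (!length(sel$choices))
    stop("[stage model_selection] no SNP yielded an estimable model")
  ranked <- rank_snps(sel$choices)

  coded <- stage("coding", {
    codings <- lapply(ranked, function(ch)
      inheritance_coding(ch$snp_id, ch$model, ch$risk_allele))
    code_matrix(cohort$genotypes, codings)
  })

  grs <- stage("optimize", optimize_grs(ranked, coded, outcome, covars))

  groups <- stage("risk_groups", assign_risk_groups(grs$scores))
  prevalence <- stage("prevalence",
                      prevalence_by_risk_group(outcome, groups$group))

  n_sel <- length(grs$selected_snps)
  alpha_corr <- bonferroni_threshold(config$alpha, max(n_sel, 1L))
  msub <- stage("minimal_subset",
                minimal_subset(grs, coded, outcome, alpha_corr))

  roc <- stage("roc_panel", {
    conv <- cbind(age = covars[, "age"], sex = covars[, "sex"],
                  education = covars[, "education"],
                  bmi = as.numeric(ph$bmi))
    conv_score <- combined_score(conv, outcome)
    conv_full <- combined_score(cbind(conv, ogrs = grs$scores), outcome)
    conv_sub <- combined_score(cbind(conv, ogrs_k = msub$scores), outcome)
    single <- vapply(c(age = "age", bmi = "bmi", tag = "tag", hdl = "hdl",
                       glucose = "glucose", sbp = "sbp", waist = "waist"),
                     function(v) auc(as.numeric(ph[[v]]), outcome),
                     numeric(1))
    list(
      auc_single = single,
      auc_ogrs = auc(grs$scores, outcome),
      auc_ogrs_k = auc(msub$scores, outcome),
      auc_conventional = auc(conv_score, outcome),
      auc_conv_plus_ogrs = auc(conv_full, outcome),
      auc_conv_plus_ogrs_k = auc(conv_sub, outcome),
      cmp_full_vs_subset = delong_test(grs$scores, msub$scores, outcome),
      cmp_conv_vs_conv_ogrs = delong_test(conv_full, conv_score, outcome),
      cmp_conv_vs_conv_ogrs_k = delong_test(conv_sub, conv_score, outcome),
      curve_ogrs = roc_curve(grs$scores, outcome)
    )
  })

  overfit <- stage("overfit_guard", {
    set.seed(substream_seed(seed, "overfit_split"))
    n <- length(outcome)
    tr <- sample(n) <= floor(n / 2)
    if (length(unique(outcome[tr])) < 2 || length(unique(outcome[!tr])) < 2)
      list(train_auc = NA_real_, test_auc = NA_real_, gap = NA_real_)
    else {
      gm_tr <- cohort$genotypes
      gm_tr$geno <- gm_tr$geno[tr, , drop = FALSE]
      gm_tr$subject_ids <- gm_tr$subject_ids[tr]
      sel_tr <- select_models(gm_tr, outcome[tr],
                              covars[tr, , drop = FALSE], snp_ids = active)
      if (!length(sel_tr$choices))
        list(train_auc = NA_real_, test_auc = NA_real_, gap = NA_real_)
      else {
        ranked_tr <- rank_snps(sel_tr$choices)
        codings_tr <- lapply(ranked_tr, function(ch)
          inheritance_coding(ch$snp_id, ch$model, ch$risk_allele))
        coded_all <- code_matrix(cohort$genotypes, codings_tr)
        g_tr <- optimize_grs(ranked_tr, coded_all[tr, , drop = FALSE],
                             outcome[tr], covars[tr, , drop = FALSE])
        s_te <- compute_grs(coded_all[!tr, , drop = FALSE],
                            g_tr$selected_snps)
        a_tr <- auc(g_tr$scores, outcome[tr])
        a_te <- auc(s_te, outcome[!tr])
        list(train_auc = a_tr, test_auc = a_te, gap = a_tr - a_te)
      }
    }
  })

  surv <- stage("survival", {
    adj <- data.frame(ogrs = as.numeric(grs$scores),
                      sex = covars[, "sex"], education = covars[, "education"])
    cont <- cox_ph_fit(ph$age, outcome, adj)
    grp <- data.frame(medium = as.numeric(groups$group == "medium"),
                      high = as.numeric(groups$group == "high"),
                      sex = covars[, "sex"], education = covars[, "education"])
    by_group <- cox_ph_fit(ph$age, outcome, grp)
    list(continuous = cont, by_group = by_group,
         cumulative_risk = cumulative_risk_by_group(ph$age, outcome,
                                                    groups$group))
  })

  distribution <- stage("distribution", {
    mw <- mann_whitney_u(grs$scores[outcome == 0], grs$scores[outcome == 1])
    by_status <- function(s) {
      x <- s
      data.frame(
        status = c("MHO", "MUO"),
        mean = c(mean(x[outcome == 0]), mean(x[outcome == 1])),
        ci_lower = c(stats::t.test(x[outcome == 0])$conf.int[1],
                     stats::t.test(x[outcome == 1])$conf.int[1]),
        ci_upper = c(stats::t.test(x[outcome == 0])$conf.int[2],
                     stats::t.test(x[outcome == 1])$conf.int[2]))
    }
    list(ogrs = by_status(grs$scores), ogrs_k = by_status(msub$scores),
         mann_whitney_p = mw$p)
  })

  bmi_groups <- assign_bmi_group(ph$bmi)
  bmi_analysis <- if (nlevels(droplevels(bmi_groups)) == 3L) {
    stage("bmi_analysis", {
      status_lab <- ifelse(outcome == 1, "unhealthy", "healthy")
      list(
        trend = trend_by_bmi_group(grs$scores, bmi_groups, status_lab,
                                   alpha_corr),
        trend_k = trend_by_bmi_group(msub$scores, bmi_groups, status_lab,
                                     alpha_corr),
        interaction = lapply(
          list(ogrs = grs$scores, ogrs_k = msub$scores),
          function(s) {
            f <- interaction_logistic(outcome, as.numeric(s),
                                      as.numeric(ph$bmi), covars)
            data.frame(
              term = c("score", "score_x_bmi"),
              or = c(unname(f$score_model$or["score"]),
                     unname(f$interaction_model$or["score_x_bmi"])),
              p = c(unname(f$score_model$p["score"]),
                    unname(f$interaction_model$p["score_x_bmi"])))
          }))
    })
  } else NULL

  summarize_status <- function() {
    vars <- intersect(c("age", "bmi", "waist", "sbp", "dbp", "tag", "hdl",
                        "glucose", "insulin", "crp"), names(ph))
    do.call(rbind, lapply(vars, function(v) data.frame(
      variable = v,
      mean_mho = mean(ph[[v]][outcome == 0]),
      mean_muo = mean(ph[[v]][outcome == 1]))))
  }

  report <- list(
    cohort_summary = list(
      n = nrow(ph), n_mho = sum(outcome == 0), n_muo = sum(outcome == 1),
      muo_prevalence_pct = 100 * mean(outcome),
      biomarker_means = summarize_status(),
      n_excluded = nrow(filt$exclusions)),
    exclusions = filt$exclusions,
    thresholds = cls$thresholds,
    hwe = hwe,
    snp_models = sel$table,
    dropped_snps = sel$dropped,
    grs = list(selected_snps = grs$selected_snps,
               n_selected = n_sel,
               trajectory = grs$trajectory,
               final_or = unname(grs$final_fit$or["ogrs"]),
               final_ci = c(unname(grs$final_fit$ci_lower["ogrs"]),
                            unname(grs$final_fit$ci_upper["ogrs"])),
               final_p = unname(grs$final_fit$p["ogrs"])),
    risk_groups = list(cut_points = groups$cut_points,
                       prevalence = prevalence$table,
                       trend_p = prevalence$trend_p),
    minimal_subset = list(k = msub$k, subset = msub$subset,
                          comparison_p = msub$comparison$p,
                          alpha_corrected = alpha_corr),
    roc = roc[names(roc) != "curve_ogrs"],
    roc_curve = roc$curve_ogrs,
    overfit_guard = overfit,
    survival = list(
      hr_continuous = surv$continuous$hr,
      hr_by_group = surv$by_group$hr,
      cumulative_risk = surv$cumulative_risk),
    distribution = distribution,
    bmi_analysis = bmi_analysis,
    provenance = list(package = "ogrs",
                      version = as.character(utils::packageVersion("ogrs")),
                      seed = seed, rule = config$rule)
  )
  class(report) <- "run_report"

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    strip <- function(x) {
      if (inherits(x, "roc_comparison")) x <- unclass(x)
      if (is.list(x) && !is.data.frame(x)) lapply(x, strip) else x
    }
    jsonlite::write_json(strip(unclass(report)),
                         file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    utils::write.table(sel$table, file.path(config$outdir, "snp_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(subject_id = names(grs$scores), ogrs = grs$scores),
      file.path(config$outdir, "scores.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("oGRS pipeline report\n")
  cat(sprintf("  cohort: n = %d (MHO %d / MUO %d, prevalence %.1f%%)\n",
              x$cohort_summary$n, x$cohort_summary$n_mho,
              x$cohort_summary$n_muo, x$cohort_summary$muo_prevalence_pct))
  cat(sprintf("  selected SNPs: %d; score OR = %.2f, p = %.3g\n",
              x$grs$n_selected, x$grs$final_or, x$grs$final_p))
  cat(sprintf("  AUC: oGRS %.3f | %d-SNP subset %.3f | conventional %.3f | conv+oGRS %.3f\n",
              x$roc$auc_ogrs, x$minimal_subset$k, x$roc$auc_ogrs_k,
              x$roc$auc_conventional, x$roc$auc_conv_plus_ogrs))
  cat(sprintf("  risk-group MUO prevalence: %s (trend p = %.3g)\n",
              paste(sprintf("%.1f%%", x$risk_groups$prevalence$prevalence_pct),
                    collapse = " / "), x$risk_groups$trend_p))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: top-level keys `rule`,
#' `hwe_alpha`, `hwe_action`, `alpha`, `outdir`, `seed`, and either a
#' `simulation` block (scalar fields of [simulation_config()]; the SNP
#' panel defaults to [default_snp_panel()]) or `genotype_csv` /
#' `phenotype_csv` paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    sim <- simulation_config(
      n_subjects = s$n_subjects %||% 398,
      baseline_logit = s$baseline_logit,
      target_prevalence = s$target_prevalence %||% 0.796,
      mode = s$mode %||% "direct_status",
      population = s$population %||% "obese",
      seed = s$seed %||% y$seed %||% 1L)
  }
  pipeline_config(
    simulation = sim,
    genotype_csv = y$genotype_csv, phenotype_csv = y$phenotype_csv,
    rule = y$rule %||% "union",
    hwe_alpha = y$hwe_alpha %||% 0.05,
    hwe_action = y$hwe_action %||% "exclude",
    alpha = y$alpha %||% 0.05,
    outdir = y$outdir, seed = y$seed %||% 1L)
}
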