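# Adjusted logistic fits per SNP under each inheritance model, model
# choice (lowest SNP-term p, ties by higher Cox & Snell R^2), and SNP
# ranking for the greedy score optimization.

#' Adjusted logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm.fit`) with
#' Wald inference: standard errors from the observed information, odds
#' ratios with `exp(beta +- 1.96 SE)` confidence intervals, and the
#' log-likelihoods needed for the Cox & Snell pseudo-R^2. An intercept is
#' always added. Fits with any `|beta| > 15` are flagged non-converged
#' (separation) and are excluded downstream.
#'
#' @param outcome 0/1 vector with both classes present.
#' @param design Numeric matrix of predictors, one column per term
#'   (no intercept column).
#' @return A `model_fit` list: `terms`, `coef`, `se`, `or`, `ci_lower`,
#'   `ci_upper`, `p`, `log_lik`, `null_log_lik`, `n`, `cox_snell_r2`,
#'   `converged`.
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.matrix(design)
  assert_binary(outcome, "outcome")
  n <- length(outcome)
  if (nrow(design) != n) stop("outcome/design dimension mismatch")
  if (n <= ncol(design) + 6L)
    stop("too few observations for the number of terms")
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  X <- cbind(`(Intercept)` = 1, design)
  fit <- suppressWarnings(stats::glm.fit(X, outcome,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  ## observed-information covariance from the final IRLS weights
  W <- fit$weights
  info <- crossprod(X * sqrt(W))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(diag(cov))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  ll <- -fit$deviance / 2
  k <- sum(outcome)
  ll0 <- k * log(k / n) + (n - k) * log(1 - k / n)
  ## separation heuristic on the slopes only: the intercept legitimately
  ## grows large when predictors are far from zero (e.g. raw scores)
  converged <- isTRUE(fit$converged) && !is.null(cov) &&
    all(is.finite(beta)) && all(abs(beta[-1]) <= 15)
  structure(list(
    terms = colnames(X), coef = beta, se = se,
    or = exp(beta), ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se), p = p,
    log_lik = ll, null_log_lik = ll0, n = n,
    cox_snell_r2 = cox_snell_r2(ll0, ll, n),
    converged = converged
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  tab <- data.frame(OR = x$or, `2.5%` = x$ci_lower, `97.5%` = x$ci_upper,
                    p = x$p, check.names = FALSE, row.names = x$terms)
  print(round(tab, 4))
  cat(sprintf("n = %d, logLik = %.3f, Cox-Snell R2 = %.4f%s\n", x$n,
              x$log_lik, x$cox_snell_r2,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Cox & Snell pseudo-R-squared
#'
#' `1 - exp((2/n) * (ll_null - ll_full))`, a likelihood-based R^2 for
#' binary-outcome models (higher is better; bounded below 1).
#'
#' @param ll_null Log-likelihood of the intercept-only model.
#' @param ll_full Log-likelihood of the fitted model; must not fall below
#'   `ll_null` by more than `tol`.
#' @param n Number of observations (>= 1).
#' @param tol Numerical tolerance for the likelihood ordering.
#' @return The pseudo-R^2 in `[0, 1)`.
#' @export
cox_snell_r2 <- function(ll_null, ll_full, n, tol = 1e-8) {
  if (n < 1) stop("n must be >= 1")
  if (ll_full < ll_null - tol)
    stop("ll_full must be >= ll_null (model cannot fit worse than null)")
  max(0, 1 - exp((2 / n) * (ll_null - ll_full)))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square with 1 df comparing observed genotype counts to the
#' expectations implied by the observed allele frequency. Monomorphic SNPs
#' are returned with `chi2 = 0`, `p = 1` and `monomorphic = TRUE`.
#'
#' @param counts Numeric length-3 vector `(n_AA, n_AB, n_BB)`.
#' @return List with `chi2`, `p`, `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))  # chi2 = 0, p = 1
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("all-zero genotype counts")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  if (q == 0 || q == 1)
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Genotype counts for one SNP relative to allele_b
#' @keywords internal
genotype_counts <- function(genotypes, snp_id) {
  j <- match(snp_id, genotypes$snp_ids)
  dose <- count_allele(genotypes$geno[, j], genotypes$alleles$allele_b[j])
  c(sum(dose == 0, na.rm = TRUE), sum(dose == 1, na.rm = TRUE),
    sum(dose == 2, na.rm = TRUE))
}

#' Select the best-fitting inheritance model for one SNP
#'
#' Fits `outcome ~ SNP_code + covariates` under the codominant, dominant
#' and recessive codings and chooses the model with the lowest SNP-term
#' Wald p-value; ties are broken by higher Cox & Snell R^2, then by the
#' fixed order codominant, dominant, recessive. The codominant model is
#' fitted as a single numeric 0/1/2 trend term by default; a 2-df
#' indicator coding (SNP-term p from the likelihood-ratio test) is
#' available via `codominant_coding = "indicator"`. Models whose coded
#' genotype is constant in the sample, or whose fit does not converge,
#' are skipped; if all three fail the SNP is dropped (`NULL` return).
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_id SNP to fit.
#' @param outcome 0/1 vector (1 = metabolically unhealthy).
#' @param covariates Numeric adjustment matrix (age, sex, education).
#' @param risk_allele Risk allele; defaults to data-driven orientation via
#'   [determine_risk_allele()].
#' @param codominant_coding `"trend"` (default) or `"indicator"`.
#' @return A `snp_model_choice` list (`snp_id`, `model`, `risk_allele`,
#'   `fit`, `rank_p`, `cox_snell_r2`, `or`, `ci`), or `NULL` when no model
#'   is estimable.
#' @export
select_inheritance_model <- function(genotypes, snp_id, outcome, covariates,
                                     risk_allele = NULL,
                                     codominant_coding = c("trend",
                                                           "indicator")) {
  codominant_coding <- match.arg(codominant_coding)
  if (is.null(risk_allele)) {
    ra <- tryCatch(
      determine_risk_allele(genotypes, snp_id, outcome, covariates),
      error = function(e) NULL)
    if (is.null(ra)) return(NULL)
    risk_allele <- ra$risk_allele
  }
  j <- match(snp_id, genotypes$snp_ids)
  al <- unlist(genotypes$alleles[j, c("allele_a", "allele_b")])
  candidates <- list()
  for (model in INHERITANCE_MODELS) {
    codes <- code_genotype(genotypes$geno[, j], risk_allele, model,
                           alleles = al)
    keep <- !is.na(codes) & !is.na(outcome)
    if (length(unique(codes[keep])) < 2L) next  # degenerate coding
    y <- outcome[keep]
    if (length(unique(y)) < 2L) next
    cv <- covariates[keep, , drop = FALSE]
    fit <- p_snp <- NULL
    if (model == "codominant" && codominant_coding == "indicator") {
      het <- as.numeric(codes[keep] == 1)
      hom <- as.numeric(codes[keep] == 2)
      design <- cbind(snp_het = het, snp_hom = hom, cv)
      if (length(unique(het)) < 2L || length(unique(hom)) < 2L) next
      fit <- tryCatch(fit_logistic(y, design), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      base <- tryCatch(fit_logistic(y, cv), error = function(e) NULL)
      if (is.null(base)) next
      p_snp <- stats::pchisq(2 * (fit$log_lik - base$log_lik), df = 2,
                             lower.tail = FALSE)
      or <- exp(unname(fit$coef["snp_hom"]))
      ci <- c(fit$ci_lower["snp_hom"], fit$ci_upper["snp_hom"])
    } else {
      design <- cbind(snp = codes[keep], cv)
      fit <- tryCatch(fit_logistic(y, design), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      p_snp <- unname(fit$p["snp"])
      or <- unname(fit$or["snp"])
      ci <- c(fit$ci_lower["snp"], fit$ci_upper["snp"])
    }
    candidates[[model]] <- list(model = model, fit = fit, rank_p = p_snp,
                                r2 = fit$cox_snell_r2, or = or,
                                ci = unname(ci))
  }
  if (!length(candidates)) return(NULL)
  ps <- vapply(candidates, `[[`, numeric(1), "rank_p")
  r2 <- vapply(candidates, `[[`, numeric(1), "r2")
  ## lowest p, then highest R2, then fixed model order (list order)
  best <- candidates[[order(ps, -r2)[1]]]
  structure(list(snp_id = snp_id, model = best$model,
                 risk_allele = risk_allele, fit = best$fit,
                 rank_p = best$rank_p, cox_snell_r2 = best$r2,
                 or = best$or, ci = best$ci),
            class = "snp_model_choice")
}

#' Fit inheritance models for every SNP in a panel
#'
#' @inheritParams select_inheritance_model
#' @param snp_ids SNPs to fit (default: all in `genotypes`).
#' @return List with `choices` (per-SNP `snp_model_choice`, dropped SNPs
#'   omitted), `dropped` (character vector), and `table` (per-SNP summary
#'   data frame: snp_id, model, risk_allele, OR, 95% CI, p, R^2).
#' @export
select_models <- function(genotypes, outcome, covariates,
                          snp_ids = genotypes$snp_ids, ...) {
  choices <- list(); dropped <- character(0)
  for (id in snp_ids) {
    ch <- select_inheritance_model(genotypes, id, outcome, covariates, ...)
    if (is.null(ch)) dropped <- c(dropped, id) else choices[[id]] <- ch
  }
  tab <- do.call(rbind, lapply(choices, function(ch) {
    data.frame(snp_id = ch$snp_id, model = ch$model,
               risk_allele = ch$risk_allele, or = ch$or,
               ci_lower = ch$ci[1], ci_upper = ch$ci[2],
               p = ch$rank_p, cox_snell_r2 = ch$cox_snell_r2,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(choices = choices, dropped = dropped, table = tab)
}

#' Rank SNP model choices by association strength
#'
#' Ascending SNP-term p-value; ties broken by higher Cox & Snell R^2, then
#' lexicographic snp_id, so the ordering is deterministic.
#'
#' @param choices List of `snp_model_choice` objects.
#' @return The list reordered.
#' @export
rank_snps <- function(choices) {
  if (!length(choices)) stop("no model choices to rank")
  ps <- vapply(choices, `[[`, numeric(1), "rank_p")
  r2 <- vapply(choices, `[[`, numeric(1), "cox_snell_r2")
  ids <- vapply(choices, `[[`, character(1), "snp_id")
  choices[order(ps, -r2, ids)]
}
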