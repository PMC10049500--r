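# Downstream inference: Cox age-of-onset model, cumulative risk curves,
# rank tests (Mann-Whitney, Jonckheere-Terpstra, exact for small samples),
# rank-based inverse-normal transformation, and interaction logistic
# models on the total population.

#' Cox proportional-hazards model on age at survey
#'
#' The exact onset age of the unhealthy phenotype is unobserved in a
#' cross-sectional survey, so age at the survey is used as the time axis:
#' metabolically unhealthy subjects are events at their survey age and
#' healthy subjects are right-censored at theirs. Efron tie handling is
#' used because ages are integer-valued and heavily tied. Fitting is
#' delegated to `survival::coxph`.
#'
#' @param age Age at survey (years, non-negative).
#' @param event 0/1, 1 = metabolically unhealthy.
#' @param covariates Data frame or numeric matrix of covariates (first
#'   columns of interest, e.g. the genetic score or risk group).
#' @return A `survival_fit` list: `hr` table (HR, 95% CI, p per term),
#'   `log_lik` (null, fitted), `n`, `n_events`, `basehaz` (baseline
#'   cumulative hazard step function as a data frame), `coxph` (the
#'   underlying fit).
#' @export
cox_ph_fit <- function(age, event, covariates) {
  stopifnot(all(age >= 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stop("no events")
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) < 2L,
                 logical(1))))
    stop("covariate with no contrast (constant column)")
  dat <- cbind(data.frame(.age = age, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.age, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  hr <- data.frame(term = rownames(s$coefficients),
                   hr = s$conf.int[, "exp(coef)"],
                   ci_lower = s$conf.int[, "lower .95"],
                   ci_upper = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(hr = hr, log_lik = fit$loglik, n = s$n,
                 n_events = s$nevent,
                 basehaz = survival::basehaz(fit, centered = TRUE),
                 coxph = fit),
            class = "survival_fit")
}

#' Cumulative risk curves by risk group
#'
#' Kaplan-Meier complement (1 - S(t)) of the age-to-event distribution,
#' one non-decreasing step function per genetic risk group.
#'
#' @inheritParams cox_ph_fit
#' @param groups Factor of group memberships partitioning the subjects.
#' @return Data frame with `group`, `age`, `cum_risk`.
#' @export
cumulative_risk_by_group <- function(age, event, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty risk group")
  sf <- survival::survfit(survival::Surv(age, event) ~ groups)
  grp_lab <- if (is.null(sf$strata)) levels(droplevels(groups))[1] else
    sub("^groups=", "", rep(names(sf$strata), sf$strata))
  data.frame(group = grp_lab, age = sf$time, cum_risk = 1 - sf$surv,
             stringsAsFactors = FALSE)
}

## pairwise Mann-Whitney count of group b over group a (ties count 1/2),
## computed from midranks: U = R_b - n_b (n_b + 1) / 2
mw_count <- function(a, b) {
  nb <- length(b)
  r <- rank(c(a, b))
  sum(r[length(a) + seq_len(nb)]) - nb * (nb + 1) / 2
}

## enumerate all distinct assignments of pooled values to ordered groups
## of the given sizes, applying `stat` to each arrangement
enumerate_group_stats <- function(values, sizes, stat) {
  out <- numeric(0)
  recurse <- function(idx, sizes, groups) {
    if (length(sizes) == 1L) {
      out[[length(out) + 1L]] <<- stat(c(groups, list(values[idx])))
      return(invisible())
    }
    picks <- utils::combn(idx, sizes[1], simplify = FALSE)
    for (p in picks)
      recurse(setdiff(idx, p), sizes[-1], c(groups, list(values[p])))
  }
  recurse(seq_along(values), sizes, list())
  out
}

#' Mann-Whitney U test
#'
#' U counts the pairs in which the second sample exceeds the first (ties
#' count 1/2). For `n_a + n_b <= exact_limit` the p-value is computed by
#' exhaustive enumeration of the permutation distribution (valid under
#' ties); otherwise a tie-corrected normal approximation is used.
#'
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (second sample tends
#'   larger) or `"less"`.
#' @param exact_limit Maximum pooled size for exact enumeration.
#' @return List with `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           alternative = c("two.sided", "greater", "less"),
                           exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  u <- mw_count(sample_a, sample_b)
  n1 <- length(sample_a); n2 <- length(sample_b); n <- n1 + n2
  if (n <= exact_limit) {
    perm <- enumerate_group_stats(c(sample_a, sample_b), c(n1, n2),
                                  function(g) mw_count(g[[1]], g[[2]]))
    eps <- 1e-9
    p_ge <- mean(perm >= u - eps); p_le <- mean(perm <= u + eps)
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(u = u, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(c(sample_a, sample_b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) stop("all values tied; Mann-Whitney variance is zero")
  z <- (u - mu) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(u = u, p = p, method = "normal")
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a variable across ordered groups. The
#' statistic is the sum of pairwise Mann-Whitney counts of every later
#' group over every earlier group. For pooled `n <= exact_limit` the
#' p-value comes from exhaustive permutation enumeration; otherwise from a
#' normal approximation with tie-corrected variance.
#'
#' @param values Numeric vector (or 0/1 outcomes for prevalence trends).
#' @param groups Ordered factor (or coercible) of group memberships; at
#'   least two non-empty groups.
#' @param alternative `"two.sided"`, `"increasing"` or `"decreasing"`.
#' @param exact_limit Maximum pooled size for exact enumeration.
#' @return A `trend_result` list: `jt`, `p`, `method`, `group_sizes`.
#' @export
jonckheere_terpstra <- function(values, groups,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                exact_limit = 12) {
  alternative <- match.arg(alternative)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two ordered groups")
  if (any(sizes == 0)) stop("empty group")
  split_vals <- split(values, groups)
  jt_stat <- function(gs) {
    k <- length(gs); s <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      s <- s + mw_count(gs[[i]], gs[[j]])
    s
  }
  jt <- jt_stat(split_vals)
  n <- length(values)
  if (length(unique(values)) < 2) stop("all values tied; no trend to test")
  if (n <= exact_limit) {
    perm <- enumerate_group_stats(values, as.integer(sizes), jt_stat)
    eps <- 1e-9
    p_ge <- mean(perm >= jt - eps); p_le <- mean(perm <= jt + eps)
    p <- switch(alternative, increasing = p_ge, decreasing = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    ni <- as.numeric(sizes)
    mu <- (n^2 - sum(ni^2)) / 4
    t <- as.numeric(table(values))
    A <- n * (n - 1) * (2 * n + 5) -
      sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(t * (t - 1) * (2 * t + 5))
    B <- sum(ni * (ni - 1) * (ni - 2)) * sum(t * (t - 1) * (t - 2))
    C <- sum(ni * (ni - 1)) * sum(t * (t - 1))
    sigma2 <- A / 72 + B / (36 * n * (n - 1) * (n - 2)) +
      C / (8 * n * (n - 1))
    if (sigma2 <= 0) stop("Jonckheere-Terpstra variance is zero")
    z <- (jt - mu) / sqrt(sigma2)
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(jt = jt, p = p, method = method,
                 group_sizes = as.integer(sizes)),
            class = "trend_result")
}

#' Rank-based two-step inverse-normal transformation
#'
#' Step 1: fractional ranks `r_i / (n + 1)` with midranks for ties.
#' Step 2: standard-normal quantiles of the fractional ranks. The
#' transform is strictly rank-preserving and maps any continuous variable
#' to approximate normality; it is applied to non-normal biomarkers
#' (screened with `stats::shapiro.test`) before parametric comparisons.
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @return Transformed numeric vector.
#' @export
templeton_two_step <- function(values) {
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 3)
    stop("need at least 3 distinct values to transform")
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm(rank(values[ok], ties.method = "average") / (n + 1))
  out
}

#' Normalize a biomarker if a normality screen rejects
#'
#' Applies [templeton_two_step()] when the Shapiro-Wilk test rejects
#' normality at `alpha`, otherwise returns the input unchanged.
#'
#' @param values Numeric vector.
#' @param alpha Screening level.
#' @return List with `values` (possibly transformed) and `transformed`.
#' @export
normalize_if_nonnormal <- function(values, alpha = 0.05) {
  ok <- !is.na(values)
  p <- stats::shapiro.test(values[ok])$p.value
  if (p < alpha)
    list(values = templeton_two_step(values), transformed = TRUE,
         shapiro_p = p)
  else list(values = values, transformed = FALSE, shapiro_p = p)
}

#' Interaction logistic models of a genetic score with BMI
#'
#' Fits, on the total population (all BMI strata), two adjusted logistic
#' models per score: the score alone and the score-by-BMI product term,
#' both adjusted for age, sex, education and BMI (and, in the interaction
#' model, the score's main effect).
#'
#' @param outcome 0/1 metabolically-unhealthy status over the total
#'   population.
#' @param score Per-subject genetic score.
#' @param bmi Numeric BMI.
#' @param covariates Numeric matrix with columns age, sex, education.
#' @return List of `model_fit`s: `score_model` (term `score`) and
#'   `interaction_model` (term `score_x_bmi`).
#' @export
interaction_logistic <- function(outcome, score, bmi, covariates) {
  if (anyNA(bmi)) stop("missing BMI")
  if (length(unique(score)) < 2L)
    stop("score has no variation; interaction model inestimable")
  score_model <- fit_logistic(
    outcome, cbind(score = score, bmi = bmi, covariates))
  interaction_model <- fit_logistic(
    outcome, cbind(score = score, bmi = bmi, score_x_bmi = score * bmi,
                   covariates))
  list(score_model = score_model, interaction_model = interaction_model)
}

#' Trend of score means across BMI strata, by metabolic status
#'
#' Within each metabolic-status stratum, reports the score mean with a
#' t-based 95% CI per ordered BMI group and the Jonckheere-Terpstra trend
#' p-value across the groups.
#'
#' @param scores Per-subject scores.
#' @param bmi_groups Ordered factor from [assign_bmi_group()].
#' @param status Character vector of status labels (healthy/unhealthy).
#' @param alpha_corrected Threshold used for the significance flag.
#' @return Data frame with one row per status x BMI group plus per-status
#'   trend p-values in the `trend_p` column.
#' @export
trend_by_bmi_group <- function(scores, bmi_groups, status,
                               alpha_corrected = 0.0026) {
  bmi_groups <- as.factor(bmi_groups)
  out <- list()
  for (s in unique(status)) {
    idx <- status == s
    if (any(table(bmi_groups[idx]) == 0))
      stop("empty BMI stratum in status group ", s)
    tr <- jonckheere_terpstra(scores[idx], bmi_groups[idx])
    for (g in levels(bmi_groups)) {
      x <- scores[idx & bmi_groups == g]
      ci <- stats::t.test(x)$conf.int
      out[[length(out) + 1L]] <- data.frame(
        status = s, bmi_group = g, n = length(x), mean = mean(x),
        ci_lower = ci[1], ci_upper = ci[2], trend_p = tr$p,
        significant = tr$p < alpha_corrected, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
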