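# ROC analysis: Mann-Whitney AUC, ROC curves, DeLong paired AUC
# comparison via placement values, and multivariable combination scores.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' `AUC = P(score_case > score_control) + 0.5 P(tie)`, computed from ranks
#' so ties are handled exactly.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 vector with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  assert_binary(labels, "labels")
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One `(1 - specificity, sensitivity)` point per distinct threshold using
#' the `score >= threshold` classification rule, with the `(0, 0)` and
#' `(1, 1)` endpoints. Tied scores collapse to a single point, so the
#' trapezoidal area under the returned polyline equals the Mann-Whitney
#' [auc()] exactly.
#'
#' @inheritParams auc
#' @return Data frame with `threshold`, `fpr`, `sensitivity`, ordered from
#'   `(0, 0)` to `(1, 1)`.
#' @export
roc_curve <- function(scores, labels) {
  assert_binary(labels, "labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                 numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
             sensitivity = c(0, sens))
}

#' Trapezoidal area under a ROC polyline
#' @keywords internal
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$sensitivity, -1) +
                           utils::tail(curve$sensitivity, -1)) / 2)
}

## DeLong placement values: V10[i] = mean_j psi(x_i, y_j) over controls,
## V01[j] = mean_i psi(x_i, y_j) over cases, psi = 1, 1/2, 0 for
## case > control, tie, case < control.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, using the placement-value (structural-component) covariance
#' estimator: `var(dAUC) = var(V10_a - V10_b)/n1 + var(V01_a - V01_b)/n0`,
#' `z = dAUC / sqrt(var)`, two-sided normal p-value.
#'
#' @param scores_a,scores_b Numeric score vectors for the same subjects.
#' @param labels 0/1 vector with both classes present.
#' @return A `roc_comparison` list: `auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  assert_binary(labels, "labels")
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  delta <- pa$auc - pb$auc
  var_delta <- stats::var(pa$v10 - pb$v10) / n1 +
    stats::var(pa$v01 - pb$v01) / n0
  if (var_delta <= 0) {
    if (abs(delta) > 1e-12)
      stop("zero DeLong variance with non-zero AUC difference")
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 var_delta = var_delta, z = z, p = p),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC_a = %.3f vs AUC_b = %.3f, dAUC = %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p))
  invisible(x)
}

#' Stratified-bootstrap paired AUC comparison
#'
#' Resamples cases and controls separately and compares the bootstrap
#' distribution of the paired AUC difference with zero (two-sided).
#' Provided as a cross-check on [delong_test()].
#'
#' @inheritParams delong_test
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `delta`, `p`, `n_boot`.
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, n_boot = 2000,
                               seed = 1L) {
  assert_binary(labels, "labels")
  set.seed(substream_seed(seed, "bootstrap_auc"))
  cases <- which(labels == 1); controls <- which(labels == 0)
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(cases, replace = TRUE), sample(controls, replace = TRUE))
    auc(scores_a[idx], labels[idx]) - auc(scores_b[idx], labels[idx])
  }, numeric(1))
  delta <- auc(scores_a, labels) - auc(scores_b, labels)
  ## two-sided p from the bootstrap null of symmetric delta around 0
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(delta = delta, p = min(1, max(p, 1 / n_boot)), n_boot = n_boot)
}

#' Multivariable combination score
#'
#' In-sample fitted probabilities from an adjusted logistic model, used as
#' the ROC score of a multi-variable panel (e.g. conventional risk factors
#' alone or combined with a genetic score). Apparent (in-sample) AUCs of
#' such scores are optimistically biased; see [cv_auc()] for an honest
#' alternative.
#'
#' @param design Numeric covariate matrix.
#' @param labels 0/1 vector.
#' @return Per-subject predicted probability.
#' @export
combined_score <- function(design, labels) {
  fit <- fit_logistic(labels, design)
  if (!fit$converged) warning("combination model flagged non-converged")
  X <- cbind(1, as.matrix(design))
  as.vector(stats::plogis(X %*% fit$coef))
}

#' Cross-validated AUC of a multivariable score
#'
#' K-fold cross-validation: the combination model is refitted on each
#' training fold and AUC is computed from held-out predictions.
#'
#' @inheritParams combined_score
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return Cross-validated AUC.
#' @export
cv_auc <- function(design, labels, k = 5, seed = 1L) {
  set.seed(substream_seed(seed, "cv_auc"))
  design <- as.matrix(design)
  folds <- sample(rep_len(seq_len(k), length(labels)))
  pred <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_logistic(labels[tr], design[tr, , drop = FALSE])
    pred[!tr] <- as.vector(stats::plogis(
      cbind(1, design[!tr, , drop = FALSE]) %*% fit$coef))
  }
  auc(pred, labels)
}
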