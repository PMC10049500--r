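# Optimized genetic risk score: unweighted sum of per-SNP inheritance
# codes, built by a single greedy pass over the p-value-ranked candidates;
# tertile risk groups; minimal-subset search by paired AUC comparison.

#' Compute an unweighted genetic risk score
#'
#' `oGRS = sum_i G_i` over the selected SNPs, where `G_i` is the coded
#' genotype (0/1/2) under the SNP's chosen inheritance model. Scores range
#' from 0 to twice the number of SNPs.
#'
#' @param coded Numeric coded matrix from [code_matrix()].
#' @param subset Character vector of SNP ids to sum (columns of `coded`).
#' @return Per-subject numeric score.
#' @export
compute_grs <- function(coded, subset) {
  if (!length(subset)) return(stats::setNames(rep(0, nrow(coded)),
                                              rownames(coded)))
  missing_cols <- setdiff(subset, colnames(coded))
  if (length(missing_cols))
    stop("subset SNPs not in coded matrix: ",
         paste(missing_cols, collapse = ", "))
  sub <- coded[, subset, drop = FALSE]
  if (anyNA(sub))
    stop("missing codes in the selected subset; run filter_complete first")
  rowSums(sub)
}

#' Greedy p-value-ordered score optimization
#'
#' Candidates are visited in ascending order of their single-SNP p-value.
#' Each candidate is trial-added to the running score and the adjusted
#' logistic model `outcome ~ score + covariates` is refitted; the candidate
#' is kept only if the score term's Wald p-value strictly decreases
#' relative to the best achieved so far ("increases the strength of
#' association"). The first candidate is accepted unconditionally and
#' rejected candidates are removed permanently (single pass, no
#' backtracking). The full trial trajectory is recorded.
#'
#' @param ranked Ranked list of `snp_model_choice` objects
#'   (see [rank_snps()]).
#' @param coded Coded matrix covering at least the ranked SNPs.
#' @param outcome 0/1 vector (1 = metabolically unhealthy).
#' @param covariates Numeric adjustment matrix (age, sex, education).
#' @return A `grs_result`: `selected_snps` (in selection order), `scores`,
#'   `trajectory` data frame (snp_id, accepted, or, ci, p), `final_fit`.
#' @export
optimize_grs <- function(ranked, coded, outcome, covariates) {
  if (!length(ranked)) stop("ranked candidate list is empty")
  assert_binary(outcome, "outcome")
  ids <- unname(vapply(ranked, `[[`, character(1), "snp_id"))
  score <- rep(0, length(outcome))
  selected <- character(0)
  best_p <- Inf
  final_fit <- NULL
  traj <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    trial <- score + coded[, ids[k]]
    fit <- tryCatch(
      fit_logistic(outcome, cbind(ogrs = trial, covariates)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    p_trial <- if (ok) unname(fit$p["ogrs"]) else NA_real_
    accept <- ok && p_trial < best_p
    traj[[k]] <- data.frame(
      snp_id = ids[k], accepted = accept,
      or = if (ok) unname(fit$or["ogrs"]) else NA_real_,
      ci_lower = if (ok) unname(fit$ci_lower["ogrs"]) else NA_real_,
      ci_upper = if (ok) unname(fit$ci_upper["ogrs"]) else NA_real_,
      p = p_trial, stringsAsFactors = FALSE)
    if (accept) {
      score <- trial
      selected <- c(selected, ids[k])
      best_p <- p_trial
      final_fit <- fit
    }
  }
  if (is.null(final_fit))
    stop("no candidate SNP yielded a converged score fit")
  structure(list(selected_snps = selected,
                 scores = stats::setNames(score, rownames(coded)),
                 trajectory = do.call(rbind, traj),
                 final_fit = final_fit),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("Optimized GRS: %d SNPs selected of %d candidates\n",
              length(x$selected_snps), nrow(x$trajectory)))
  cat("score term: OR =", round(unname(x$final_fit$or["ogrs"]), 3),
      sprintf("(%.3f-%.3f), p = %.3g\n",
              unname(x$final_fit$ci_lower["ogrs"]),
              unname(x$final_fit$ci_upper["ogrs"]),
              unname(x$final_fit$p["ogrs"])))
  invisible(x)
}

#' Tertile genetic risk groups
#'
#' Cut points are the nearest-rank 1/3 and 2/3 quantiles of the score;
#' subjects tied with a cut point are all assigned to the lower group, so
#' group sizes can differ by the number of boundary ties.
#'
#' @param scores Per-subject numeric scores (n >= 3, at least 3 distinct
#'   values).
#' @return A `risk_groups` list: `group` (ordered factor low < medium <
#'   high) and `cut_points`.
#' @export
assign_risk_groups <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 subjects")
  if (length(unique(scores)) < 3)
    stop("fewer than 3 distinct score values; tertiles are undefined")
  srt <- sort(unname(scores))
  n <- length(srt)
  cuts <- c(low = srt[ceiling(n / 3)], medium = srt[ceiling(2 * n / 3)])
  group <- ifelse(scores <= cuts["low"], "low",
                  ifelse(scores <= cuts["medium"], "medium", "high"))
  structure(list(group = factor(group, levels = c("low", "medium", "high"),
                                ordered = TRUE),
                 cut_points = cuts),
            class = "risk_groups")
}

#' Minimal SNP subset with equivalent discrimination
#'
#' Finds the smallest k such that the score built from the first k selected
#' SNPs (in selection order) discriminates no worse than the full optimized
#' score: the DeLong paired AUC comparison between the k-SNP score and the
#' full score has `p > alpha_corrected`. Prefixes of the selection order
#' are searched, mirroring "the top-ranked SNPs"; k equal to the full size
#' always qualifies (a score compared with itself gives p = 1).
#'
#' @param result A `grs_result`.
#' @param coded Coded matrix covering the selected SNPs.
#' @param outcome 0/1 vector.
#' @param alpha_corrected Significance threshold for the paired comparison,
#'   typically Bonferroni-corrected (see [bonferroni_threshold()]).
#' @return List with `k`, `subset`, `scores`, `comparison`
#'   (the `roc_comparison` for the chosen k).
#' @export
minimal_subset <- function(result, coded, outcome, alpha_corrected = 0.0026) {
  stopifnot(inherits(result, "grs_result"),
            alpha_corrected > 0, alpha_corrected < 1)
  full <- result$scores
  sel <- result$selected_snps
  for (k in seq_along(sel)) {
    sub_scores <- compute_grs(coded, sel[seq_len(k)])
    cmp <- delong_test(full, sub_scores, outcome)
    if (cmp$p > alpha_corrected)
      return(list(k = k, subset = sel[seq_len(k)], scores = sub_scores,
                  comparison = cmp))
  }
  ## unreachable: k = length(sel) compares the score with itself (p = 1)
  list(k = length(sel), subset = sel, scores = full,
       comparison = delong_test(full, full, outcome))
}
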