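# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-seed for a named random substream
#'
#' All stochastic components of the package draw their seed from one master
#' seed plus a stream name, so that a single `seed` argument reproduces a
#' whole pipeline run while the individual generators stay independently
#' reproducible.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. `"genotypes"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

assert_binary <- function(x, name = deparse(substitute(x))) {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("'%s' must be a 0/1 vector", name), call. = FALSE)
  if (length(unique(x)) < 2L)
    stop(sprintf("'%s' must contain both classes", name), call. = FALSE)
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' Computes `alpha / m` and rounds to a given number of significant figures,
#' the convention used when a single corrected threshold is quoted for a
#' family of `m` tests (e.g. 0.05 / 19 tests -> 0.0026).
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests in the family (positive integer).
#' @param sig_figs Significant figures for the quoted threshold; `NULL`
#'   returns the unrounded value.
#' @return The corrected threshold as a single number.
#' @examples
#' bonferroni_threshold(0.05, 19)  # 0.0026
#' @export
bonferroni_threshold <- function(alpha = 0.05, m, sig_figs = 2) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(m), m >= 1, m == round(m))
  thr <- alpha / m
  if (!is.null(sig_figs)) thr <- signif(thr, sig_figs)
  thr
}
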