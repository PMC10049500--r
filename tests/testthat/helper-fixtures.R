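# Shared fixtures and independent oracles for the test suite.

# one-causal-SNP panel for parameter-recovery simulations
single_snp_panel <- function(model = "dominant", log_or = log(2),
                             maf = 0.3) {
  snp_panel(snp_id = "rs_test", gene = "GENE1",
            allele_a = "A", allele_b = "G", maf = maf,
            causal_flag = TRUE, true_model = model, true_log_or = log_or)
}

# small deterministic genotype matrix from explicit cells
make_gm <- function(cells, snp_ids, allele_a, allele_b) {
  m <- matrix(cells, ncol = length(snp_ids),
              dimnames = list(sprintf("P%02d", seq_len(length(cells) /
                                                         length(snp_ids))),
                              snp_ids))
  genotype_matrix(m, data.frame(snp_id = snp_ids, allele_a = allele_a,
                                allele_b = allele_b,
                                stringsAsFactors = FALSE))
}

# a phenotype row with healthy defaults, overridable per field
subject_row <- function(...) {
  base <- data.frame(
    subject_id = "P01", age = 50, sex = "female", education = 2,
    bmi = 33, waist = 80, sbp = 120, dbp = 75, tag = 1.0, hdl = 1.6,
    glucose = 4.5, insulin = 100, crp = 10,
    on_bp_meds = FALSE, on_diabetes_meds = FALSE, on_lipid_meds = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# independent per-cell recoding oracle: counts risk alleles by string
# splitting and applies the model map by explicit branching
oracle_recode_cell <- function(cell, risk, model) {
  if (is.na(cell)) return(NA_real_)
  alleles <- strsplit(cell, "/", fixed = TRUE)[[1]]
  copies <- as.numeric((alleles[1] == risk) + (alleles[2] == risk))
  if (model == "codominant") return(copies)
  if (model == "dominant") return(if (copies >= 1) 2 else 0)
  if (copies == 2) 2 else 0
}

# brute-force Mann-Whitney count by double loop
oracle_mw_count <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (y > x) + 0.5 * (y == x)
  s
}

# exact permutation p for a two-group statistic by enumeration over all
# n! orderings (independent of the package's combination-based recursion)
oracle_perm_pvalue <- function(values, sizes, stat_fun, observed,
                               tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  perms <- all_permutations(seq_along(values))
  stats <- apply(perms, 1, function(idx) {
    v <- values[idx]
    groups <- split(v, rep(seq_along(sizes), sizes))
    stat_fun(groups)
  })
  eps <- 1e-9
  p_ge <- mean(stats >= observed - eps)
  p_le <- mean(stats <= observed + eps)
  if (tail == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

all_permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
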