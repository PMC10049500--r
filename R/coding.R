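# Genotype container and inheritance-model coding.
#
# Inheritance codes, with the risk-allele copy number r in {0, 1, 2}:
#   codominant: 0, 1, 2
#   dominant:   0, 2, 2  (carriers coded 2, exactly as the score is defined)
#   recessive:  0, 0, 2

INHERITANCE_MODELS <- c("codominant", "dominant", "recessive")

#' Construct a genotype matrix
#'
#' @param geno Character matrix of unphased allele pairs (`"A/G"`), subjects
#'   in rows, SNPs in columns (dimnames required); `NA` marks a missing
#'   genotype.
#' @param alleles Data frame with `snp_id`, `allele_a`, `allele_b`, one row
#'   per column of `geno`.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(geno, alleles) {
  stopifnot(is.matrix(geno), is.character(geno),
            !is.null(rownames(geno)), !is.null(colnames(geno)),
            all(c("snp_id", "allele_a", "allele_b") %in% names(alleles)))
  alleles <- as.data.frame(alleles)[, c("snp_id", "allele_a", "allele_b")]
  if (!identical(colnames(geno), alleles$snp_id))
    stop("geno columns and alleles$snp_id must match in order")
  for (j in seq_len(ncol(geno))) {
    ok <- c(NA_character_,
            allele_pair_strings(alleles$allele_a[j], alleles$allele_b[j]))
    bad <- !(geno[, j] %in% ok)
    if (any(bad))
      stop(sprintf("SNP %s: genotype '%s' uses undeclared alleles",
                   alleles$snp_id[j], geno[which(bad)[1], j]))
  }
  structure(list(subject_ids = rownames(geno), snp_ids = colnames(geno),
                 alleles = alleles, geno = geno),
            class = "genotype_matrix")
}

allele_pair_strings <- function(a, b) {
  c(paste(a, a, sep = "/"), paste(a, b, sep = "/"),
    paste(b, a, sep = "/"), paste(b, b, sep = "/"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs, %d missing calls\n",
              length(x$subject_ids), length(x$snp_ids),
              sum(is.na(x$geno))))
  invisible(x)
}

#' Count copies of an allele in unphased genotype strings
#' @keywords internal
count_allele <- function(genotype, allele) {
  parts <- strsplit(genotype, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || anyNA(p)) return(NA_integer_)
    sum(p == allele)
  }, integer(1))
}

#' Code genotypes under an inheritance model
#'
#' Maps risk-allele copy number to the numeric code of the chosen model:
#' codominant (0,1,2), dominant (0,2,2) and recessive (0,0,2). Dominant
#' carriers are coded 2, not 1 -- this is how the unweighted score is
#' defined and it sets the score's scale (each SNP contributes 0-2).
#'
#' @param genotype Character vector of allele pairs (`"A/G"`); `NA` allowed.
#' @param risk_allele Single nucleotide; which allele counts as the risk
#'   allele.
#' @param model One of `"codominant"`, `"dominant"`, `"recessive"`.
#' @param alleles Optional length-2 character vector of the SNP's declared
#'   alleles; when supplied, genotypes using other alleles are an error.
#' @return Integer vector of codes in `{0, 1, 2}` (`NA` preserved).
#' @examples
#' code_genotype("A/G", "A", "codominant")  # 1
#' code_genotype("A/G", "A", "dominant")    # 2
#' code_genotype("A/G", "A", "recessive")   # 0
#' @export
code_genotype <- function(genotype, risk_allele, model, alleles = NULL) {
  model <- match.arg(model, INHERITANCE_MODELS)
  if (!is.null(alleles)) {
    ok <- c(NA_character_, allele_pair_strings(alleles[1], alleles[2]))
    if (any(!genotype %in% ok))
      stop("genotype uses alleles outside the declared pair")
    if (!risk_allele %in% alleles)
      stop("risk_allele is not one of the declared alleles")
  }
  r <- count_allele(genotype, risk_allele)
  map <- switch(model,
                codominant = c(0L, 1L, 2L),
                dominant   = c(0L, 2L, 2L),
                recessive  = c(0L, 0L, 2L))
  out <- rep(NA_integer_, length(r))
  ok <- !is.na(r)
  out[ok] <- map[r[ok] + 1L]
  out
}

#' Construct an inheritance coding for one SNP
#'
#' @param snp_id SNP identifier.
#' @param model Inheritance model.
#' @param risk_allele Risk allele nucleotide.
#' @return An `inheritance_coding` list with the genotype-to-code map.
#' @export
inheritance_coding <- function(snp_id, model, risk_allele) {
  model <- match.arg(model, INHERITANCE_MODELS)
  code_map <- switch(model,
                     codominant = c(`0` = 0L, `1` = 1L, `2` = 2L),
                     dominant   = c(`0` = 0L, `1` = 2L, `2` = 2L),
                     recessive  = c(`0` = 0L, `1` = 0L, `2` = 2L))
  structure(list(snp_id = snp_id, model = model, risk_allele = risk_allele,
                 code_map = code_map),
            class = "inheritance_coding")
}

#' Determine a SNP's risk allele from the data
#'
#' Fits an adjusted logistic model of the outcome on the additive dosage of
#' `allele_b` and orients the SNP so the fitted odds ratio for the risk
#' allele exceeds 1: `allele_b` if its OR > 1, otherwise `allele_a`. The
#' paper-style workflow assumes literature risk alleles; this makes the
#' orientation reproducible from the data alone, and a known risk allele
#' can be forced via codings built with [inheritance_coding()].
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_id SNP to orient.
#' @param outcome 0/1 vector (1 = metabolically unhealthy).
#' @param covariates Numeric adjustment matrix (age, sex, education).
#' @return List with `risk_allele`, `or_allele_b`, `converged`.
#' @export
determine_risk_allele <- function(genotypes, snp_id, outcome, covariates) {
  j <- match(snp_id, genotypes$snp_ids)
  if (is.na(j)) stop("unknown snp_id: ", snp_id)
  al <- genotypes$alleles[j, ]
  dose <- count_allele(genotypes$geno[, j], al$allele_b)
  keep <- !is.na(dose)
  fit <- fit_logistic(outcome[keep],
                      cbind(dose = dose[keep], covariates[keep, , drop = FALSE]))
  if (!fit$converged) stop("risk-allele fit did not converge for ", snp_id)
  or_b <- fit$or["dose"]
  list(risk_allele = if (or_b > 1) al$allele_b else al$allele_a,
       or_allele_b = unname(or_b), converged = fit$converged)
}

#' Apply inheritance codings to a genotype matrix
#'
#' @param genotypes A [genotype_matrix()].
#' @param codings List of [inheritance_coding()] objects, one per SNP to
#'   code; every requested SNP must have a coding.
#' @return Numeric matrix of codes (subjects x SNPs), `NA` preserved.
#' @export
code_matrix <- function(genotypes, codings) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- vapply(codings, `[[`, character(1), "snp_id")
  if (anyDuplicated(ids)) stop("duplicate codings")
  missing_snp <- setdiff(ids, genotypes$snp_ids)
  if (length(missing_snp))
    stop("codings refer to unknown SNPs: ",
         paste(missing_snp, collapse = ", "))
  out <- matrix(NA_real_, nrow = length(genotypes$subject_ids),
                ncol = length(ids),
                dimnames = list(genotypes$subject_ids, ids))
  for (k in seq_along(codings)) {
    cd <- codings[[k]]
    j <- match(cd$snp_id, genotypes$snp_ids)
    out[, k] <- code_genotype(genotypes$geno[, j], cd$risk_allele, cd$model,
                              alleles = unlist(genotypes$alleles[j, c("allele_a",
                                                                      "allele_b")]))
  }
  out
}
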