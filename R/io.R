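# Readers and writers for the package's plain-text interchange formats:
# genotype CSV (cells "A/G", "." missing), phenotype CSV, coded-matrix TSV,
# and VCFv4.2 import/export of a panel.

#' Write a genotype matrix as CSV
#'
#' Rows are subjects, columns rsIDs, cells unphased allele pairs such as
#' `"A/G"`; missing genotypes are written as `"."`. The allele declaration
#' is written alongside as `<path>.alleles.csv`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(genotypes, path) {
  m <- genotypes$geno
  m[is.na(m)] <- "."
  df <- data.frame(subject_id = genotypes$subject_ids, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(genotypes$alleles, paste0(path, ".alleles.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype CSV
#'
#' @param path CSV written by [write_genotype_csv()] (or following the
#'   same convention).
#' @param alleles Optional allele declaration data frame (`snp_id`,
#'   `allele_a`, `allele_b`); defaults to `<path>.alleles.csv`, and when
#'   neither is available the two alleles observed per SNP are used.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(path, alleles = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") stop("first column must be subject_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "."] <- NA_character_
  rownames(m) <- df$subject_id
  if (is.null(alleles)) {
    side <- paste0(path, ".alleles.csv")
    if (file.exists(side)) {
      alleles <- utils::read.csv(side, stringsAsFactors = FALSE)
    } else {
      alleles <- do.call(rbind, lapply(colnames(m), function(id) {
        obs <- sort(unique(unlist(strsplit(stats::na.omit(m[, id]), "/"))))
        if (length(obs) == 1) obs <- c(obs, setdiff(c("A", "C", "G", "T"),
                                                    obs)[1])
        if (length(obs) != 2) stop("SNP ", id, " is not biallelic")
        data.frame(snp_id = id, allele_a = obs[1], allele_b = obs[2],
                   stringsAsFactors = FALSE)
      }))
    }
  }
  alleles <- alleles[match(colnames(m), alleles$snp_id), ]
  genotype_matrix(m, alleles)
}

#' Write a phenotype table as CSV
#'
#' One row per subject; the documented header is the column convention of
#' [generate_cohort()] (subject_id, age, sex, education, biomarkers,
#' medication flags).
#'
#' @param phenotypes Phenotype data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#' @param path CSV path.
#' @return Data frame with logical medication flags.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (fl in intersect(c("on_bp_meds", "on_diabetes_meds", "on_lipid_meds"),
                       names(df)))
    df[[fl]] <- as.logical(df[[fl]])
  df
}

#' Export a genotype matrix as VCFv4.2
#'
#' Unphased GT fields; `allele_a` is written as REF and `allele_b` as ALT.
#' Positions are synthetic (sequential on chromosome 1) since the panel
#' carries no coordinates.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  al <- genotypes$alleles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$subject_ids),
                     collapse = "\t")), con)
  for (j in seq_along(genotypes$snp_ids)) {
    g <- genotypes$geno[, j]
    parts <- strsplit(g, "/", fixed = TRUE)
    gt <- vapply(parts, function(p) {
      if (length(p) != 2 || anyNA(p)) return("./.")
      idx <- ifelse(p == al$allele_a[j], "0", "1")
      paste(sort(idx), collapse = "/")
    }, character(1))
    gt[is.na(g)] <- "./."
    writeLines(paste(c("1", j, al$snp_id[j], al$allele_a[j],
                       al$allele_b[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Import genotypes from a VCF
#'
#' Reads GT fields with `vcfR` (unphased or phased separators accepted);
#' multi-allelic records are rejected.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), fix[, "ID"]))
  for (j in seq_len(nrow(gt))) {
    ref <- fix[j, "REF"]; alt <- fix[j, "ALT"]
    codes <- gt[j, ]
    parts <- strsplit(codes, "[/|]")
    geno[, j] <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || anyNA(p)) return(NA_character_)
      paste(ifelse(p == "0", ref, alt), collapse = "/")
    }, character(1))
  }
  genotype_matrix(geno, data.frame(snp_id = fix[, "ID"],
                                   allele_a = fix[, "REF"],
                                   allele_b = fix[, "ALT"],
                                   stringsAsFactors = FALSE))
}

#' Write a coded matrix as TSV
#' @param coded Numeric coded matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coded_tsv <- function(coded, path) {
  df <- data.frame(subject_id = rownames(coded), coded,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
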