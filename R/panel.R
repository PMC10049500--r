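# SNP panel: identity, alleles, MAF, trait category, and (for simulation
# only) ground-truth causal structure.

#' Construct a SNP panel
#'
#' A SNP panel describes the variants available to the risk-score analysis:
#' identity, the two alleles, the minor-allele frequency used for simulation,
#' and a trait category (obesity, lipid or glucose metabolism). The
#' simulation-truth columns (`causal_flag`, `true_model`, `true_log_or`)
#' define the generative model of [generate_status()] and are ignored by all
#' analysis stages; `allele_b` is the risk-increasing allele of every causal
#' SNP in the generator.
#'
#' @param snp_id Character vector of variant identifiers (rsIDs).
#' @param gene Character vector of gene symbols.
#' @param allele_a,allele_b Single-character nucleotide codes; must differ
#'   per SNP.
#' @param maf Minor-allele (allele_b) frequency, in (0, 0.5].
#' @param trait_category One of `"obesity"`, `"lipid"`, `"glucose"` per SNP.
#' @param causal_flag Logical; simulation truth.
#' @param true_model Inheritance model of the simulated effect:
#'   `"codominant"`, `"dominant"` or `"recessive"`.
#' @param true_log_or Log odds ratio per model code unit; must be 0 for
#'   non-causal SNPs.
#' @return A `snp_panel` data frame with one row per SNP.
#' @seealso [default_snp_panel()]
#' @export
snp_panel <- function(snp_id, gene, allele_a, allele_b, maf,
                      trait_category = "obesity",
                      causal_flag = FALSE,
                      true_model = "codominant",
                      true_log_or = 0) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    gene = as.character(gene),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b),
    maf = as.numeric(maf),
    trait_category = as.character(trait_category),
    causal_flag = as.logical(causal_flag),
    true_model = as.character(true_model),
    true_log_or = as.numeric(true_log_or),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  nucs <- c("A", "C", "G", "T")
  if (anyDuplicated(panel$snp_id))
    stop("duplicate snp_id in panel", call. = FALSE)
  if (any(panel$allele_a == panel$allele_b))
    stop("allele_a and allele_b must differ", call. = FALSE)
  if (!all(panel$allele_a %in% nucs) || !all(panel$allele_b %in% nucs))
    stop("alleles must be single nucleotide codes A/C/G/T", call. = FALSE)
  if (any(panel$maf <= 0 | panel$maf > 0.5))
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (!all(panel$trait_category %in% c("obesity", "lipid", "glucose")))
    stop("trait_category must be obesity, lipid or glucose", call. = FALSE)
  if (!all(panel$true_model %in% c("codominant", "dominant", "recessive")))
    stop("true_model must be codominant, dominant or recessive",
         call. = FALSE)
  if (any(!panel$causal_flag & panel$true_log_or != 0))
    stop("true_log_or must be 0 for non-causal SNPs", call. = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Default 67-SNP simulation panel
#'
#' A synthetic panel of 67 SNPs in 44 genes implicated in obesity, lipid
#' metabolism and glucose homeostasis (23 obesity, 22 lipid, 22 glucose
#' variants). Nineteen SNPs in fifteen genes are flagged causal for the
#' metabolically unhealthy phenotype, with mixed inheritance modes and
#' log odds ratios concentrated in four lead variants (rs10838687/MADD,
#' rs693/APOB, rs1111875/HHEX, rs2000813/LIPG). Allele assignments, MAFs
#' and effect sizes are synthetic defaults chosen to be realistic for
#' common metabolic-trait variants; they are not literature look-ups.
#'
#' @return A `snp_panel` with 67 rows.
#' @export
default_snp_panel <- function() {
  entry <- function(id, gene, cat) c(id, gene, cat)
  tab <- rbind(
    ## obesity-associated variants (23)
    entry("rs9939609",  "FTO",     "obesity"),
    entry("rs17817449", "FTO",     "obesity"),
    entry("rs1558902",  "FTO",     "obesity"),
    entry("rs17782313", "MC4R",    "obesity"),
    entry("rs571312",   "MC4R",    "obesity"),
    entry("rs7799039",  "LEP",     "obesity"),
    entry("rs1137101",  "LEPR",    "obesity"),
    entry("rs6548238",  "TMEM18",  "obesity"),
    entry("rs10938397", "GNPDA2",  "obesity"),
    entry("rs925946",   "BDNF",    "obesity"),
    entry("rs10767664", "BDNF",    "obesity"),
    entry("rs7498665",  "SH2B1",   "obesity"),
    entry("rs2815752",  "NEGR1",   "obesity"),
    entry("rs11084753", "KCTD15",  "obesity"),
    entry("rs10913469", "SEC16B",  "obesity"),
    entry("rs7647305",  "ETV5",    "obesity"),
    entry("rs7138803",  "FAIM2",   "obesity"),
    entry("rs6232",     "PCSK1",   "obesity"),
    entry("rs7566605",  "INSIG2",  "obesity"),
    entry("rs1801282",  "PPARG",   "obesity"),
    entry("rs266729",   "ADIPOQ",  "obesity"),
    entry("rs659366",   "UCP2",    "obesity"),
    entry("rs660339",   "UCP2",    "obesity"),
    ## lipid-metabolism variants (22)
    entry("rs693",      "APOB",    "lipid"),
    entry("rs562338",   "APOB",    "lipid"),
    entry("rs676210",   "APOB",    "lipid"),
    entry("rs2000813",  "LIPG",    "lipid"),
    entry("rs708272",   "CETP",    "lipid"),
    entry("rs1800775",  "CETP",    "lipid"),
    entry("rs3764261",  "CETP",    "lipid"),
    entry("rs328",      "LPL",     "lipid"),
    entry("rs12678919", "LPL",     "lipid"),
    entry("rs1800588",  "LIPC",    "lipid"),
    entry("rs662799",   "APOA5",   "lipid"),
    entry("rs3135506",  "APOA5",   "lipid"),
    entry("rs429358",   "APOE",    "lipid"),
    entry("rs7412",     "APOE",    "lipid"),
    entry("rs599839",   "SORT1",   "lipid"),
    entry("rs2954029",  "TRIB1",   "lipid"),
    entry("rs2131925",  "ANGPTL3", "lipid"),
    entry("rs7679",     "PLTP",    "lipid"),
    entry("rs17145738", "MLXIPL",  "lipid"),
    entry("rs1260326",  "GCKR",    "lipid"),
    entry("rs10838687", "MADD",    "lipid"),
    entry("rs2338104",  "KCTD10",  "lipid"),
    ## glucose-homeostasis variants (22)
    entry("rs1111875",  "HHEX",    "glucose"),
    entry("rs5015480",  "HHEX",    "glucose"),
    entry("rs7923837",  "HHEX",    "glucose"),
    entry("rs7903146",  "TCF7L2",  "glucose"),
    entry("rs4506565",  "TCF7L2",  "glucose"),
    entry("rs13266634", "SLC30A8", "glucose"),
    entry("rs11558471", "SLC30A8", "glucose"),
    entry("rs5219",     "KCNJ11",  "glucose"),
    entry("rs5210",     "KCNJ11",  "glucose"),
    entry("rs10830963", "MTNR1B",  "glucose"),
    entry("rs1387153",  "MTNR1B",  "glucose"),
    entry("rs7754840",  "CDKAL1",  "glucose"),
    entry("rs7756992",  "CDKAL1",  "glucose"),
    entry("rs10811661", "CDKN2B",  "glucose"),
    entry("rs2383208",  "CDKN2B",  "glucose"),
    entry("rs2237892",  "KCNQ1",   "glucose"),
    entry("rs2237897",  "KCNQ1",   "glucose"),
    entry("rs163184",   "KCNQ1",   "glucose"),
    entry("rs11071657", "C2CD4B",  "glucose"),
    entry("rs5400",     "SLC2A2",  "glucose"),
    entry("rs10423928", "GIPR",    "glucose"),
    entry("rs7944584",  "MADD",    "glucose")
  )
  n <- nrow(tab)
  allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T",
                           "A", "T", "C", "G"),
                         ncol = 2, byrow = TRUE)
  pair_idx <- rep_len(seq_len(nrow(allele_pairs)), n)
  mafs <- rep_len(c(0.12, 0.21, 0.33, 0.45, 0.27, 0.38, 0.17, 0.30,
                    0.42, 0.24), n)

  ## Simulation truth: 19 causal SNPs in 15 genes; effects front-loaded on
  ## the four lead variants, moderate for the rest.
  causal <- c(
    rs10838687 = 0.65, rs693      = 0.60, rs1111875 = 0.58,
    rs2000813  = 0.55, rs562338   = 0.42, rs7923837 = 0.40,
    rs708272   = 0.38, rs328      = 0.38, rs12678919 = 0.35,
    rs1800588  = 0.35, rs266729   = 0.33, rs1801282 = 0.33,
    rs11071657 = 0.30, rs10811661 = 0.30, rs10423928 = 0.28,
    rs5400     = 0.28, rs13266634 = 0.26, rs2338104 = 0.25,
    rs7944584  = 0.25
  )
  causal_model <- c(
    rs10838687 = "dominant",   rs693      = "codominant",
    rs1111875  = "dominant",   rs2000813  = "recessive",
    rs562338   = "dominant",   rs7923837  = "recessive",
    rs708272   = "codominant", rs328      = "dominant",
    rs12678919 = "recessive",  rs1800588  = "dominant",
    rs266729   = "codominant", rs1801282  = "dominant",
    rs11071657 = "recessive",  rs10811661 = "dominant",
    rs10423928 = "codominant", rs5400     = "dominant",
    rs13266634 = "recessive",  rs2338104  = "dominant",
    rs7944584  = "recessive"
  )
  ## recessive effects need a common risk homozygote to be detectable at
  ## cohort scale, so causal recessive SNPs get MAF >= 0.3
  causal_maf <- c(
    rs10838687 = 0.30, rs693      = 0.48, rs1111875 = 0.40,
    rs2000813  = 0.45, rs562338   = 0.30, rs7923837 = 0.42,
    rs708272   = 0.44, rs328      = 0.25, rs12678919 = 0.40,
    rs1800588  = 0.28, rs266729   = 0.30, rs1801282 = 0.22,
    rs11071657 = 0.38, rs10811661 = 0.25, rs10423928 = 0.35,
    rs5400     = 0.30, rs13266634 = 0.44, rs2338104 = 0.35,
    rs7944584  = 0.36
  )
  ids <- tab[, 1]
  is_causal <- ids %in% names(causal)
  mafs[is_causal] <- causal_maf[ids[is_causal]]
  model <- rep("codominant", n)
  model[is_causal] <- causal_model[ids[is_causal]]
  logor <- rep(0, n)
  logor[is_causal] <- causal[ids[is_causal]]

  snp_panel(
    snp_id = ids, gene = tab[, 2],
    allele_a = allele_pairs[pair_idx, 1],
    allele_b = allele_pairs[pair_idx, 2],
    maf = mafs, trait_category = tab[, 3],
    causal_flag = is_causal, true_model = model, true_log_or = logor
  )
}
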