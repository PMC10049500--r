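# Score arithmetic, the greedy optimization contract, tertile groups,
# and the minimal-subset search.

test_that("scores are plain row sums over the selected codes", {
  coded <- matrix(c(2, 0, 1, 2,
                    0, 0, 0, 0,
                    2, 2, 2, 2), nrow = 3, byrow = TRUE,
                  dimnames = list(c("P1", "P2", "P3"),
                                  c("s1", "s2", "s3", "s4")))
  expect_equal(unname(compute_grs(coded, c("s1", "s2", "s3", "s4"))),
               c(5, 0, 8))
  expect_equal(unname(compute_grs(coded, character(0))), c(0, 0, 0))
  coded[1, 2] <- NA
  expect_error(compute_grs(coded, c("s1", "s2")), "missing")
  expect_error(compute_grs(coded, "nope"), "not in coded")
  # brute-force per-subject loop oracle on random matrices
  set.seed(51)
  for (rep in 1:20) {
    m <- matrix(sample(0:2, 30, TRUE), 6, 5,
                dimnames = list(paste0("P", 1:6), paste0("s", 1:5)))
    sub <- sample(colnames(m), sample(1:5, 1))
    by_hand <- vapply(seq_len(6), function(i) sum(m[i, sub]), numeric(1))
    expect_equal(unname(compute_grs(m, sub)), by_hand)
  }
})

test_that("greedy optimization keeps its acceptance contract", {
  set.seed(52)
  cfg <- simulation_config(n_subjects = 398, seed = 52)
  co <- generate_cohort(cfg)
  y <- as.integer(co$phenotypes$status == "MUO")
  cv <- adjustment_matrix(co$phenotypes)
  sel <- select_models(co$genotypes, y, cv)
  ranked <- rank_snps(sel$choices)
  codings <- lapply(ranked, function(ch)
    inheritance_coding(ch$snp_id, ch$model, ch$risk_allele))
  coded <- code_matrix(co$genotypes, codings)
  g <- optimize_grs(ranked, coded, y, cv)

  # selected = accepted trajectory rows, in candidate (rank) order
  expect_identical(g$selected_snps,
                   g$trajectory$snp_id[g$trajectory$accepted])
  # accepted p-values strictly decrease
  acc_p <- g$trajectory$p[g$trajectory$accepted]
  expect_true(all(diff(acc_p) < 0))
  # first candidate always accepted
  expect_true(g$trajectory$accepted[1])
  # scores are bounded by twice the panel size and match a recompute
  expect_true(all(g$scores >= 0 & g$scores <= 2 * length(g$selected_snps)))
  expect_equal(g$scores, compute_grs(coded, g$selected_snps))
  # deterministic: same inputs, same result
  g2 <- optimize_grs(ranked, coded, y, cv)
  expect_identical(g$selected_snps, g2$selected_snps)
  expect_identical(g$trajectory, g2$trajectory)
})

test_that("a single candidate is selected with a one-row trajectory", {
  set.seed(53)
  panel <- single_snp_panel("dominant", 0.7, maf = 0.3)
  cfg <- simulation_config(n_subjects = 400, panel = panel,
                           baseline_logit = 0, seed = 53)
  co <- generate_cohort(cfg)
  y <- as.integer(co$phenotypes$status == "MUO")
  cv <- adjustment_matrix(co$phenotypes)
  sel <- select_models(co$genotypes, y, cv)
  ranked <- rank_snps(sel$choices)
  coded <- code_matrix(co$genotypes, list(inheritance_coding(
    ranked[[1]]$snp_id, ranked[[1]]$model, ranked[[1]]$risk_allele)))
  g <- optimize_grs(ranked, coded, y, cv)
  expect_equal(length(g$selected_snps), 1L)
  expect_equal(nrow(g$trajectory), 1L)
})

test_that("tertile groups cut at nearest-rank thirds with ties going low", {
  rg <- assign_risk_groups(1:9)
  expect_equal(as.vector(table(rg$group)), c(3, 3, 3))
  expect_equal(unname(rg$cut_points), c(3, 6))
  expect_error(assign_risk_groups(rep(5, 10)), "distinct")
  expect_error(assign_risk_groups(c(1, 2)), "3 subjects")
  # ties at the first cut all land in the low group
  s <- c(1, 2, 2, 2, 5, 6, 7, 8, 9)
  rg2 <- assign_risk_groups(s)
  expect_true(all(rg2$group[s == 2] == "low"))
  expect_equal(sum(as.vector(table(rg2$group))), length(s))
  # exhaustive small-vector check of the partition invariant
  set.seed(54)
  for (rep in 1:30) {
    v <- sample(0:5, sample(6:12, 1), TRUE)
    if (length(unique(v)) < 3) next
    rg3 <- assign_risk_groups(v)
    expect_equal(length(rg3$group), length(v))
    expect_false(anyNA(rg3$group))
    # groups respect the score ordering
    expect_true(max(v[rg3$group == "low"]) <=
                  min(c(v[rg3$group == "medium"], Inf)))
  }
})

test_that("minimal subset terminates at the full score with p = 1", {
  set.seed(55)
  n <- 200
  coded <- matrix(sample(0:2, n * 3, TRUE), n, 3,
                  dimnames = list(sprintf("P%03d", 1:n),
                                  c("s1", "s2", "s3")))
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * rowSums(coded)))
  cv <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
              education = sample(1:3, n, TRUE))
  mk <- function(id) structure(
    list(snp_id = id, model = "codominant", risk_allele = "A", fit = NULL,
         rank_p = 0.01, cox_snell_r2 = 0.01, or = 1.5, ci = c(1, 2)),
    class = "snp_model_choice")
  g <- optimize_grs(list(mk("s1"), mk("s2"), mk("s3")), coded, y, cv)
  # with alpha so strict nothing smaller qualifies, the search must still
  # terminate; the full set compared with itself gives p = 1
  ms <- minimal_subset(g, coded, y, alpha_corrected = 1 - 1e-12)
  expect_lte(ms$k, length(g$selected_snps))
  full_cmp <- delong_test(g$scores, g$scores, y)
  expect_equal(full_cmp$p, 1)
  expect_equal(full_cmp$delta, 0)
  # Bonferroni threshold for 19 tests reproduces the published 0.0026
  expect_equal(bonferroni_threshold(0.05, 19), 0.0026)
})
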