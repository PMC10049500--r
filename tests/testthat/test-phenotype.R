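# Classification must reproduce the combined Wildman/Meigs rules exactly,
# including strict/inclusive boundaries and percentile thresholds.

test_that("HOMA-IR follows the defining formula", {
  expect_equal(compute_homa_ir(22.5, 1.0), 1.0)
  expect_equal(compute_homa_ir(10, 4.5), 2.0)
  expect_error(compute_homa_ir(-1, 4.5), "positive")
  expect_true(is.na(compute_homa_ir(NA, 4.5)))
  expect_true(is.na(compute_homa_ir(0, 4.5)))
})

test_that("Wildman counts reproduce the published group profiles", {
  # unhealthy-group means: elevated BP, TAG, glucose; low-ish HDL for a woman
  muo <- subject_row(sex = "female", sbp = 141, dbp = 85, tag = 2.21,
                     hdl = 1.20, glucose = 5.56, waist = 112.9)
  w <- classify_wildman(muo, homa_p90 = 1e6, crp_p90 = 1e6)
  expect_equal(w$count, 3L)  # BP, TAG, HDL < 1.3 (glucose 5.56 < 5.6)
  expect_true(w$flag)

  # healthy-group means: nothing fires for a man
  mho <- subject_row(sex = "male", sbp = 127.3, dbp = 80.7, tag = 1.20,
                     hdl = 1.45, glucose = 4.33)
  w2 <- classify_wildman(mho, homa_p90 = 1e6, crp_p90 = 1e6)
  expect_equal(w2$count, 0L)
  expect_false(w2$flag)

  # every criterion just below threshold -> count 0
  eps <- 1e-9
  border <- subject_row(sex = "male", sbp = 130 - eps, dbp = 85 - eps,
                        tag = 1.7 - eps, hdl = 1.0, glucose = 5.6 - eps,
                        insulin = 1, crp = 1)
  w3 <- classify_wildman(border, homa_p90 = 10, crp_p90 = 10)
  expect_equal(w3$count, 0L)
})

test_that("Meigs waist criterion is strictly greater than the cut-off", {
  m1 <- classify_meigs(subject_row(sex = "male", waist = 103, sbp = 135,
                                   tag = 1.8))
  expect_equal(m1$count, 3L)
  expect_true(m1$flag)
  # WC exactly 102 does not fire for a man
  m2 <- classify_meigs(subject_row(sex = "male", waist = 102, sbp = 135,
                                   tag = 1.8))
  expect_equal(m2$count, 2L)
  expect_false(m2$flag)  # ">2" boundary: exactly 2 criteria is healthy
})

test_that("combined rule is the union and records which rule fired", {
  thr <- list(homa_p90 = 1e6, crp_p90 = 1e6)
  healthy <- subject_row()
  cl <- classify_cohort(healthy, thr)
  expect_equal(cl$status, "MHO")
  expect_equal(cl$rule_fired, "neither")

  # Wildman fires alone (2 criteria; Meigs needs > 2)
  wonly <- subject_row(sbp = 150, tag = 2.0)
  cl2 <- classify_cohort(wonly, thr)
  expect_equal(cl2$status, "MUO")
  expect_equal(cl2$rule_fired, "wildman")
  # intersection mode demotes a single-rule subject
  expect_equal(classify_cohort(wonly, thr, rule = "intersection")$status,
               "MHO")

  # published unhealthy profile fires both rules
  muo <- subject_row(sex = "female", sbp = 141, dbp = 85, tag = 2.21,
                     hdl = 1.20, glucose = 5.56, waist = 112.9)
  cl3 <- classify_cohort(muo, thr)
  expect_equal(cl3$status, "MUO")
  expect_equal(cl3$rule_fired, "both")
})

test_that("worsening any biomarker never decreases a criterion count", {
  set.seed(31)
  worsen <- list(sbp = 25, dbp = 15, tag = 1.5, glucose = 2, waist = 20,
                 crp = 50, insulin = 300, hdl = -0.6)
  for (rep in 1:40) {
    ph <- subject_row(sex = sample(c("male", "female"), 1),
                      sbp = runif(1, 110, 150), dbp = runif(1, 70, 95),
                      tag = runif(1, 0.8, 2.5), hdl = runif(1, 0.8, 1.8),
                      glucose = runif(1, 3.5, 7), waist = runif(1, 70, 115),
                      insulin = runif(1, 50, 400), crp = runif(1, 5, 80))
    v <- sample(names(worsen), 1)
    ph2 <- ph
    ph2[[v]] <- ph2[[v]] + worsen[[v]]
    w1 <- classify_wildman(ph, 200, 60); w2 <- classify_wildman(ph2, 200, 60)
    m1 <- classify_meigs(ph); m2 <- classify_meigs(ph2)
    expect_gte(w2$count, w1$count)
    expect_gte(m2$count, m1$count)
  }
})

test_that("BMI strata use half-open intervals", {
  expect_equal(as.character(assign_bmi_group(c(24.99, 25, 29.99, 30))),
               c("normal", "overweight", "overweight", "obese"))
  expect_error(assign_bmi_group(NA), "missing")
  expect_error(assign_bmi_group(5), "sanity")
})

test_that("nearest-rank 90th percentile flags the right share of the stratum", {
  set.seed(13)
  n <- 398
  ph <- do.call(rbind, lapply(seq_len(n), function(i)
    subject_row(subject_id = sprintf("P%03d", i))))
  ph$insulin <- sample(seq(50, 500, length.out = n))  # distinct values
  ph$crp <- sample(seq(1, 100, length.out = n))
  thr <- cohort_thresholds(ph)
  homa <- compute_homa_ir(ph$insulin, ph$glucose)
  n_flagged <- sum(homa >= thr$homa_p90)
  expect_true(n_flagged %in% c(floor(0.1 * n), ceiling(0.1 * n)))
})

test_that("complete-case filter removes and logs exactly the right subjects", {
  cfg <- simulation_config(n_subjects = 60, seed = 14)
  co <- generate_cohort(cfg)
  # untouched cohort passes through unchanged
  res0 <- filter_complete(co)
  expect_equal(nrow(res0$cohort$phenotypes), 60)
  expect_equal(nrow(res0$exclusions), 0)
  # one missing genotype, one missing biomarker
  co$genotypes$geno[3, 5] <- NA
  co$phenotypes$tag[7] <- NA
  res <- filter_complete(co)
  expect_equal(nrow(res$cohort$phenotypes), 58)
  expect_setequal(res$exclusions$subject_id,
                  co$phenotypes$subject_id[c(3, 7)])
  expect_setequal(res$exclusions$reason,
                  c("incomplete genotype", "incomplete phenotype"))
  # truth stays aligned with the retained subjects
  expect_equal(length(res$cohort$truth$status), 58)
})
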