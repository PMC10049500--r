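# Rank tests against exact-permutation oracles, the inverse-normal
# transform, Cox partial likelihood against hand enumeration, and the
# interaction models.

test_that("Mann-Whitney U matches brute force and exact enumeration", {
  # U counts second-sample wins; extremes and identity
  m <- mann_whitney_u(1:5, 6:10)
  expect_equal(m$u, 25)
  expect_equal(mann_whitney_u(6:10, 1:5)$u, 0)
  expect_equal(m$p, 2 / choose(10, 5))  # both tails of the extreme
  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1)
  # rank-based count equals the double-loop oracle, with ties
  set.seed(71)
  for (rep in 1:20) {
    a <- sample(1:5, sample(3:6, 1), TRUE)
    b <- sample(1:5, sample(3:6, 1), TRUE)
    expect_equal(mann_whitney_u(a, b)$u, oracle_mw_count(a, b))
  }
  # exact p equals wilcox.test's exact p when there are no ties
  set.seed(72)
  for (rep in 1:5) {
    a <- sample(1:50, 5); b <- sample(51:100, 4)
    pool <- sample(c(a, b)); a <- pool[1:5]; b <- pool[6:9]
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(b, a, exact = TRUE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Jonckheere-Terpstra matches its definition and a permutation oracle", {
  g3 <- factor(rep(1:3, each = 2), ordered = TRUE)
  jt_max <- jonckheere_terpstra(c(1, 2, 3, 4, 5, 6), g3,
                                alternative = "increasing")
  expect_equal(jt_max$jt, 12)
  expect_equal(jt_max$p, 1 / 90)  # the single perfectly ordered arrangement
  jt_rev <- jonckheere_terpstra(c(5, 6, 3, 4, 1, 2), g3,
                                alternative = "increasing")
  expect_equal(jt_rev$jt, 0)
  # two groups: JT reduces to the Mann-Whitney U of group 2 over group 1
  set.seed(73)
  for (rep in 1:10) {
    a <- sample(1:6, 5, TRUE); b <- sample(1:6, 4, TRUE)
    jt <- jonckheere_terpstra(c(a, b), rep(1:2, c(5, 4)))
    expect_equal(jt$jt, mann_whitney_u(a, b)$u)
  }
  # exact p against full-permutation enumeration (with ties)
  vals <- c(1, 2, 2, 3, 4, 4, 5)
  sizes <- c(2, 2, 3)
  g <- rep(1:3, sizes)
  ours <- jonckheere_terpstra(vals, g, alternative = "increasing")
  jt_fun <- function(groups) {
    s <- 0
    for (i in 1:2) for (j in (i + 1):3)
      s <- s + oracle_mw_count(groups[[i]], groups[[j]])
    s
  }
  p_oracle <- oracle_perm_pvalue(vals, sizes, jt_fun, ours$jt,
                                 tail = "greater")
  expect_equal(ours$p, p_oracle, tolerance = 1e-12)
  # JT = sum of pairwise MW counts on random instances (large-sample path)
  set.seed(74)
  x <- sample(1:8, 40, TRUE)
  grp <- factor(sample(1:3, 40, TRUE), ordered = TRUE)
  jt_big <- jonckheere_terpstra(x, grp)
  by_hand <- 0
  for (i in 1:2) for (j in (i + 1):3)
    by_hand <- by_hand + oracle_mw_count(x[grp == levels(grp)[i]],
                                         x[grp == levels(grp)[j]])
  expect_equal(jt_big$jt, by_hand)
  expect_equal(jt_big$method, "normal")
  expect_error(jonckheere_terpstra(rep(1, 10), rep(1:2, 5)), "tied")
})

test_that("two-step inverse-normal transform hits closed-form quantiles", {
  out3 <- templeton_two_step(c(10, 20, 30))
  expect_equal(out3, qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(out3[2], 0)
  # strictly rank-preserving
  set.seed(75)
  x <- rlnorm(200)
  y <- templeton_two_step(x)
  expect_equal(cor(x, y, method = "spearman"), 1)
  # heavily skewed input becomes screenably normal
  big <- rlnorm(5000, sdlog = 2)
  expect_gt(shapiro.test(templeton_two_step(big))$p.value, 0.01)
  expect_error(templeton_two_step(c(1, 1, 1, 1)), "distinct")
  # the screen triggers the transform only for non-normal input
  skewed <- normalize_if_nonnormal(rlnorm(300))
  expect_true(skewed$transformed)
  gauss <- normalize_if_nonnormal(rnorm(300))
  expect_false(gauss$transformed)
})

test_that("Cox partial likelihood matches hand enumeration on six subjects", {
  # all events, distinct times: risk sets shrink one by one
  time <- 1:6
  event <- rep(1, 6)
  x <- c(1, 0, 1, 0, 0, 1)
  beta <- 0.5
  hand <- 0
  for (i in 1:6) {
    risk <- i:6  # subjects still at risk at time i (sorted by time)
    hand <- hand + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  fit0 <- survival::coxph(survival::Surv(time, event) ~ x, init = beta,
                          control = survival::coxph.control(iter.max = 0))
  expect_equal(fit0$loglik[2], hand, tolerance = 1e-10)
  # and the packaged fit maximizes it: fitted loglik >= hand value
  fit <- cox_ph_fit(time, event, data.frame(x = x))
  expect_gte(fit$log_lik[2], hand)
  expect_equal(fit$n_events, 6)
})

test_that("Cox fit recovers a rate ratio of 2 and flags degenerate input", {
  set.seed(76)
  n <- 5000
  grp <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = ifelse(grp == 1, 2, 1))
  fit <- cox_ph_fit(t, rep(1, n), data.frame(grp = grp))
  se <- sqrt(diag(fit$coxph$var))
  expect_lt(abs(log(fit$hr$hr) - log(2)), 3 * se)
  expect_error(cox_ph_fit(t, rep(1, n), data.frame(grp = rep(1, n))),
               "contrast")
  expect_error(cox_ph_fit(t, rep(0, n), data.frame(grp = grp)), "events")
})

test_that("cumulative risk curves are Kaplan-Meier complements", {
  # four subjects, all events at distinct ages: jumps of 1/4
  cr <- cumulative_risk_by_group(c(40, 50, 60, 70), rep(1, 4),
                                 rep("low", 4))
  expect_equal(cr$cum_risk, c(0.25, 0.5, 0.75, 1))
  expect_true(all(diff(cr$cum_risk) >= 0))
  # a group with no events stays at zero
  cr2 <- cumulative_risk_by_group(c(40, 50, 60, 70), c(1, 1, 0, 0),
                                  rep(c("a", "b"), each = 2))
  expect_true(all(cr2$cum_risk[cr2$group == "b"] == 0))
  # simulated hazard gradient orders the curves at the median age
  set.seed(77)
  n <- 900
  g <- rep(c("low", "medium", "high"), each = n / 3)
  rate <- c(low = 0.01, medium = 0.02, high = 0.04)[g]
  age <- 30 + rexp(n, rate)
  cr3 <- cumulative_risk_by_group(pmin(age, 90), rep(1, n),
                                  factor(g, c("low", "medium", "high")))
  at_age <- function(grp, a) {
    sub <- cr3[cr3$group == grp & cr3$age <= a, ]
    if (nrow(sub)) max(sub$cum_risk) else 0
  }
  med <- median(pmin(age, 90))
  expect_lt(at_age("low", med), at_age("medium", med))
  expect_lt(at_age("medium", med), at_age("high", med))
})

test_that("interaction model recovers a product-term effect near OR 1.07", {
  set.seed(78)
  n <- 20000
  score <- sample(0:8, n, TRUE)
  bmi <- rnorm(n, 28, 4)
  cv <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
              education = sample(1:3, n, TRUE))
  eta <- 0.07 * score * bmi
  y <- rbinom(n, 1, plogis(eta - mean(eta)))
  fits <- interaction_logistic(y, score, bmi, cv)
  b <- fits$interaction_model$coef["score_x_bmi"]
  se <- fits$interaction_model$se["score_x_bmi"]
  expect_lt(abs(b - 0.07), 3 * se)
  expect_error(interaction_logistic(y, rep(2, n), bmi, cv), "variation")
  expect_error(interaction_logistic(y, score, c(NA, bmi[-1]), cv),
               "missing BMI")
})

test_that("interaction product term holds its type-I error under the null", {
  set.seed(79)
  rej <- mean(replicate(200, {
    n <- 1500
    score <- sample(0:8, n, TRUE)
    bmi <- rnorm(n, 28, 4)
    cv <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                education = sample(1:3, n, TRUE))
    y <- rbinom(n, 1, plogis(-1 + 0.1 * score + 0.03 * bmi))
    fits <- interaction_logistic(y, score, bmi, cv)
    fits$interaction_model$p["score_x_bmi"] < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.10)
})

test_that("score trends across BMI strata are detected per status stratum", {
  set.seed(80)
  n <- 600
  bmi <- c(rnorm(n / 3, 22, 1.5), rnorm(n / 3, 27, 1.4), rnorm(n / 3, 33, 2))
  bmi <- pmax(pmin(bmi, 45), 16)
  grp <- assign_bmi_group(bmi)
  status <- sample(c("healthy", "unhealthy"), n, TRUE)
  scores <- 20 + 2 * as.integer(grp) + rnorm(n, 0, 2)  # clear gradient
  tr <- trend_by_bmi_group(scores, grp, status)
  expect_equal(nrow(tr), 6)  # 2 statuses x 3 strata
  expect_true(all(tr$trend_p < 0.001))
  expect_true(all(tr$ci_lower < tr$mean & tr$mean < tr$ci_upper))
  # means increase along the gradient within each stratum
  for (s in unique(status)) {
    m <- tr$mean[tr$status == s]
    expect_true(all(diff(m) > 0))
  }
})
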