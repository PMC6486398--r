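test_that("group comparisons behave at the contract boundaries", {
  df2 <- data.frame(v = c(1, 2, 3, 101, 102, 103),
                    g = rep(c("a", "b"), each = 3))
  expect_lt(group_compare(df2, "v", "g", "welch")$p_value, 0.001)

  same <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(group_compare(same, "v", "g", "wilcoxon")$p_value, 1)

  k3 <- data.frame(v = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"),
                                                   each = 3))
  expect_equal(group_compare(k3, "v", "g", "kruskal")$statistic, 0)

  expect_error(group_compare(data.frame(v = 1:3, g = "a"), "v", "g",
                             "welch"), "two")
  expect_error(group_compare(k3, "v", "g", "wilcoxon"), "two groups")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))             # never decreases
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # order preserved
  }
})

test_that("Spearman correlation handles monotone and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # n = 5 distinct ranks with one adjacent swap: 1 - 6*2/(5*24) = 0.9
  expect_equal(spearman_cor(1:5, c(1, 2, 3, 5, 4))$rho, 0.9)
  expect_error(spearman_cor(rep(2, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:3), "3 complete")
})

test_that("surv_cutpoint finds the separating threshold", {
  set.seed(31)
  # covariate perfectly separates short from long survivors around 10,
  # and the survival times themselves are fully separated, so any split
  # mixing the clusters dilutes the log-rank statistic
  n <- 40
  x <- c(runif(n / 2, 0, 4), runif(n / 2, 16, 20))
  time <- c(runif(n / 2, 10, 50), runif(n / 2, 500, 1000))
  d <- data.frame(time = time, event = 1, x = x)
  cp <- surv_cutpoint(d, "time", "event", "x")
  expect_gte(cp$threshold, max(x[seq_len(n / 2)]))
  expect_lte(cp$threshold, min(x[n / 2 + seq_len(n / 2)]))
  expect_equal(cp$n_low, n / 2)

  # two distinct covariate values: the only admissible split
  d2 <- data.frame(time = rexp(20) + 1, event = 1,
                   x = rep(c(1, 3), each = 10))
  cp2 <- surv_cutpoint(d2, "time", "event", "x")
  expect_equal(cp2$threshold, 2)

  expect_error(surv_cutpoint(data.frame(time = rexp(20) + 1, event = 1,
                                        x = 5), "time", "event", "x"),
               "constant")
})

test_that("surv_cutpoint equals the exhaustive enumeration oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(30:200, 1)
    d <- sim_surv_cohort(n, beta = runif(1, -1, 1), censor_ratio = 0.4,
                         x = rnorm(n))
    d$time <- d$time + 1e-9
    cp <- surv_cutpoint(d, "time", "event", "x")
    orc <- oracle_cutpoint(d$time, d$event, d$x)
    expect_equal(cp$cutpoint_value, orc$cut[which.max(orc$std)],
                 tolerance = 1e-12)
    expect_equal(cp$statistic, max(orc$std), tolerance = 1e-9)
    # every admissible candidate matches, not just the argmax
    expect_equal(cp$candidates$statistic, orc$std, tolerance = 1e-9)
  }
})

test_that("log-rank test statistics behave on degenerate groups", {
  d <- data.frame(time = rep(c(5, 10, 15, 20), 2), event = 1,
                  g = rep(c("a", "b"), each = 4))
  km <- km_logrank(d, "time", "event", "g")
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1, tolerance = 1e-9)

  cens <- data.frame(time = 1, event = 0, g = rep(c("a", "b"), 5))
  expect_equal(km_logrank(cens, "time", "event", "g")$chisq, 0)

  expect_error(km_logrank(data.frame(time = 1:4, event = 1, g = "a"),
                          "time", "event", "g"), "two groups")
})

test_that("log-rank detects a strong planted hazard ratio", {
  set.seed(77)
  hits <- 0
  for (i in 1:20) {
    d <- sim_surv_cohort(400, beta = log(3), censor_ratio = 0.2)
    d$g <- ifelse(d$x == 1, "high", "low")
    if (km_logrank(d, "time", "event", "g")$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("cox_fit recovers parameters and flags degenerate designs", {
  set.seed(19)
  d <- sim_surv_cohort(500, beta = log(2), censor_ratio = 0.3 / 0.7)
  fit <- cox_fit(d, "time", "event", "x")
  td <- tidy(fit)
  expect_gt(td$hr, 1.6)
  expect_lt(td$hr, 2.5)
  expect_true(td$conf_low <= td$hr && td$hr <= td$conf_high)
  expect_equal(glance(fit)$aic,
               -2 * fit$fit$loglik[2] + 2, tolerance = 1e-12)

  d$x2 <- d$x
  expect_warning(cox_fit(d, "time", "event", c("x", "x2")), "Collinear")
  d$k <- 1
  expect_error(cox_fit(d, "time", "event", "k"), "constant")
  tiny <- d[1:4, ]
  tiny$event <- c(1, 0, 0, 0)
  expect_error(cox_fit(tiny, "time", "event", "x"), "few events")
})

test_that("stepwise selection is greedy on AIC and handles one candidate", {
  set.seed(23)
  d <- sim_surv_cohort(300, beta = log(3), censor_ratio = 0.3)
  d$noise1 <- rnorm(300); d$noise2 <- rnorm(300)
  fw <- stepwise_cox(d, "time", "event", c("x", "noise1", "noise2"),
                     direction = "forward")
  bw <- stepwise_cox(d, "time", "event", c("x", "noise1", "noise2"),
                     direction = "backward")
  expect_true("x" %in% fw$selected)
  expect_true("x" %in% bw$selected)
  expect_equal(fw$trace$action[1], "start")
  expect_true(all(diff(fw$trace$aic) < 0))

  # single candidate: kept iff AIC improves over the null model
  one <- stepwise_cox(d, "time", "event", "x", direction = "forward")
  null_aic <- one$trace$aic[1]
  solo <- cox_fit(d, "time", "event", "x")
  if (solo$aic < null_aic) {
    expect_identical(one$selected, "x")
  } else {
    expect_length(one$selected, 0)
  }
})

test_that("stepwise agrees with exhaustive best-subset search", {
  set.seed(29)
  agree <- 0; runs <- 12
  for (i in seq_len(runs)) {
    d <- sim_surv_cohort(150, beta = log(2.5), censor_ratio = 0.25)
    d$n1 <- rnorm(150); d$n2 <- rnorm(150)
    cands <- c("x", "n1", "n2")
    best <- oracle_best_subset(d, "time", "event", cands)
    fw <- stepwise_cox(d, "time", "event", cands, "forward")
    bw <- stepwise_cox(d, "time", "event", cands, "backward")
    found <- setequal(fw$selected, best$set) ||
      setequal(bw$selected, best$set)
    if (found) agree <- agree + 1
    # greedy can never beat the exhaustive optimum
    expect_gte(min(fw$aic, bw$aic), best$aic - 1e-9)
  }
  expect_gte(agree, runs - 1)
})
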