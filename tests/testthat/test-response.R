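# Miller-Payne dichotomization, strata, logistic regression, cohorts.

test_that("Miller-Payne dichotomization and strata boundaries", {
  expect_true(mp_responder(4))
  expect_true(mp_responder(5))
  expect_false(mp_responder(3))
  expect_equal(mp_responder(c(1, 4, 2, 5)), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(mp_responder(6), class = "invalid_record")
  expect_error(mp_responder(0), class = "invalid_record")

  expect_equal(as.character(stil_stratum(c(0, 9.9, 10, 49.9, 50, 100))),
               c("low", "low", "intermediate", "intermediate",
                 "high", "high"))
  expect_error(stratum_config(low_cut = 50, high_cut = 10),
               class = "invalid_config")
})

test_that("IRLS logistic matches the 2x2 closed form and glm", {
  # 30/20 responders among exposed, 20/30 among unexposed
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30))
  fit <- fit_logistic(cbind(x = x), y)
  row <- fit$or_table[fit$or_table$term == "x", ]
  expect_equal(row$or, 2.25, tolerance = 1e-6)
  se <- sqrt(1 / 30 + 1 / 20 + 1 / 20 + 1 / 30)
  expect_equal(row$se, se, tolerance = 1e-6)
  expect_equal(row$ci_low, exp(log(2.25) - qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_equal(row$ci_high, exp(log(2.25) + qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_equal(round(c(row$ci_low, row$ci_high), 3), c(1.011, 5.008))
  # independent oracle: stats::glm on a richer design
  set.seed(3)
  X <- cbind(a = rnorm(300), b = rbinom(300, 1, 0.4))
  eta <- -0.4 + 0.8 * X[, 1] - 0.5 * X[, 2]
  yy <- rbinom(300, 1, plogis(eta))
  mine <- fit_logistic(X, yy)
  ref <- glm(yy ~ X, family = binomial())
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(mine$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  # log-likelihood is non-decreasing across IRLS iterations
  expect_true(all(diff(mine$loglik) > -1e-8))
})

test_that("logistic fit flags separation and bad designs", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x  # complete separation
  expect_error(fit_logistic(cbind(x = x), y), class = "separation_error")
  expect_error(fit_logistic(cbind(x = x, x2 = x), y),
               class = "invalid_config")
  expect_error(fit_logistic(cbind(x = x), x + 0.5),
               class = "invalid_config")
})

test_that("cohort generator obeys its logistic link and design counts", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 7)
  expect_identical(nrow(co), 203L)
  expect_identical(sum(co$subtype == "HER2_positive"), 148L)
  expect_identical(sum(co$subtype == "TNBC"), 55L)
  expect_identical(co$responder, co$mp_grade >= 4)
  expect_true(all(co$mp_grade %in% 1:5))
  # null model: responder rate independent of sTIL stratum
  null_cfg <- cohort_config(n_total = 5000, n_her2 = 3650, n_tnbc = 1350,
                            beta_stil = 0)
  co0 <- generate_cohort(null_cfg,
                         sample_slide_truths(5000, seed = 11), seed = 12)
  tab <- table(stil_stratum(co0$true_stil), co0$responder)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("logistic refits recover the generating sTIL coefficient", {
  cfg <- cohort_config(n_total = 5000, n_her2 = 3650, n_tnbc = 1350,
                       beta_stil = 0.3)
  hits <- 0L
  for (r in 1:100) {
    co <- generate_cohort(cfg, sample_slide_truths(5000, seed = 1000 + r),
                          seed = 2000 + r)
    fit <- fit_logistic(cbind(stil10 = co$true_stil / 10,
                              tnbc = as.numeric(co$subtype == "TNBC")),
                        co$responder)
    row <- fit$or_table[fit$or_table$term == "stil10", ]
    lo <- row$estimate - qnorm(0.975) * row$se
    hi <- row$estimate + qnorm(0.975) * row$se
    if (lo <= 0.3 && 0.3 <= hi) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("response analysis reports strata contrasts and degenerate cases", {
  cfg <- cohort_config(n_total = 1000, n_her2 = 730, n_tnbc = 270,
                       beta_stil = 0.4)
  co <- generate_cohort(cfg, sample_slide_truths(1000, seed = 3), seed = 4)
  rep_all <- response_analysis(co, "initial", "all")
  expect_true(all(rep_all$or_table$available))
  expect_gt(rep_all$mean_responder, rep_all$mean_nonresponder)
  # monotone dose: high-vs-low OR exceeds intermediate-vs-low OR
  ors <- setNames(rep_all$or_table$or, rep_all$or_table$contrast)
  expect_gt(ors[["high_vs_low"]], ors[["intermediate_vs_low"]])
  # subset partition: HER2 + TNBC counts sum to the overall count
  rep_h <- response_analysis(co, "initial", "HER2_positive")
  rep_t <- response_analysis(co, "initial", "TNBC")
  expect_identical(rep_h$n + rep_t$n, rep_all$n)
  # all-identical scores: t and ORs unavailable, no crash
  co2 <- co
  co2$stil_initial <- 20
  rep2 <- response_analysis(co2, "initial", "all")
  expect_null(rep2$t_test)
  expect_false(any(rep2$or_table$available))
})

test_that("null cohorts yield near-unit stratum odds ratios", {
  cfg <- cohort_config(n_total = 5000, n_her2 = 3650, n_tnbc = 1350,
                       beta_stil = 0)
  covered <- c(intermediate_vs_low = 0L, high_vs_low = 0L)
  point_ok <- 0L
  for (r in 1:100) {
    co <- generate_cohort(cfg, sample_slide_truths(5000, seed = 300 + r),
                          seed = 600 + r)
    rep0 <- response_analysis(co, "initial", "all")
    # each contrast's 95% Wald interval covers the true null OR of 1
    covered <- covered + (rep0$or_table$ci_low <= 1 &
                            rep0$or_table$ci_high >= 1)
    # and point estimates sit near 1 (within 2 asymptotic SEs of the
    # sparser high-vs-low contrast, about +/- 25% on the OR scale)
    if (all(rep0$or_table$or > 0.75 & rep0$or_table$or < 1.33)) {
      point_ok <- point_ok + 1L
    }
  }
  expect_true(all(covered >= 90L))
  expect_gte(point_ok, 90L)
})
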