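# Agreement statistics: CCC, COV, Bland-Altman, McNemar, mean tests.

test_that("Lin's CCC matches its closed form and definition", {
  expect_equal(lins_ccc(1:10, 1:10)$estimate, 1)
  # worked example with biased (/n) moments
  cc <- lins_ccc(c(10, 20, 30), c(20, 30, 40))
  expect_equal(cc$estimate, 2 * (200 / 3) / ((200 / 3) + (200 / 3) + 100),
               tolerance = 1e-12)
  expect_equal(cc$estimate, 0.5714, tolerance = 1e-4)
  # brute-force evaluation of the definition on random vectors
  set.seed(50)
  x <- rnorm(50, 20, 8)
  y <- 0.8 * x + rnorm(50, 3, 4)
  n <- 50
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  brute <- 2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  expect_equal(lins_ccc(x, y)$estimate, brute, tolerance = 1e-12)
  expect_error(lins_ccc(rep(5, 10), rep(7, 10)), class = "degenerate_stat")
  expect_error(lins_ccc(1:2, 2:3), class = "invalid_config")
})

test_that("CCC is bounded by Pearson r and is shift/scale invariant", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(30, 25, 10)
    y <- rnorm(30, 20, 12) + 0.5 * x
    cc <- lins_ccc(x, y)$estimate
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
    # common shift and common positive rescaling leave CCC unchanged
    expect_equal(lins_ccc(x + 7, y + 7)$estimate, cc, tolerance = 1e-12)
    expect_equal(lins_ccc(x * 2.5, y * 2.5)$estimate, cc,
                 tolerance = 1e-12)
  }
})

test_that("CCC interval is ordered around the estimate", {
  set.seed(31)
  x <- rnorm(80, 20, 10)
  y <- x + rnorm(80, 2, 6)
  cc <- lins_ccc(pmax(x, 0), pmax(y, 0))
  expect_lte(cc$ci_low, cc$estimate)
  expect_gte(cc$ci_high, cc$estimate)
  expect_identical(cc$n, 80L)
})

test_that("pairwise CCC handles identical, missing and sparse readers", {
  set.seed(9)
  base <- runif(30, 0, 60)
  m <- cbind(A = base, B = base, C = base + rnorm(30, 0, 5))
  m[m < 0] <- 0
  p <- panel_of(m)
  pw <- pairwise_ccc(p)
  expect_equal(pw$estimate["A", "B"], 1)
  expect_equal(pw$estimate, t(pw$estimate))
  expect_equal(unname(diag(pw$estimate)), rep(1, 3))
  # a reader sharing no slides with another: unavailable cell, no crash
  m2 <- m
  m2[1:15, "A"] <- NA
  m2[16:30, "B"] <- NA
  pw2 <- pairwise_ccc(panel_of(m2))
  expect_true(is.na(pw2$estimate["A", "B"]))
  expect_identical(pw2$n["A", "B"], 0L)
  # composition identity: panel mean vs a reader reproduces lins_ccc
  pm <- rowMeans(m)
  expect_equal(lins_ccc(pm, m[, "C"])$estimate,
               lins_ccc(rowMeans(m), m[, "C"])$estimate)
})

test_that("per-case COV follows the sample-SD/mean convention", {
  m <- rbind(c(10, 20, 30), c(15, 15, 15), c(0, 0, 0))
  res <- cov_per_case(panel_of(m))
  expect_equal(res$per_slide$cov, c(0.5, 0, 0))
  # single-reader slides are excluded with a warning
  m2 <- rbind(c(10, 20, NA), c(15, NA, NA))
  expect_warning(res2 <- cov_per_case(panel_of(m2)), "excluded")
  expect_identical(nrow(res2$per_slide), 1L)
  # automated readers never enter the COV
  m3 <- cbind(m, DL = c(99, 99, 99))
  res3 <- cov_per_case(panel_of(m3, automated = TRUE))
  expect_equal(res3$per_slide$cov, res$per_slide$cov)
})

test_that("Bland-Altman limits use interpolated 2.5/97.5 percentiles", {
  ba0 <- bland_altman(1:20, 1:20)
  expect_equal(c(ba0$mean_diff, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  # d = 1..100 under the h = (n-1)p + 1 convention
  d <- 1:100
  ba <- bland_altman(d + 100, rep(100, 100))
  expect_equal(ba$loa_low, 3.475)
  expect_equal(ba$loa_high, 97.525)
  expect_equal(ba$mean_diff, 50.5)
  # ~95% of a large normal sample falls inside its own limits
  set.seed(77)
  x <- rnorm(2000, 10, 5)
  y <- rnorm(2000, 8, 5)
  bb <- bland_altman(x, y)
  frac <- mean(x - y >= bb$loa_low & x - y <= bb$loa_high)
  expect_lt(abs(frac - 0.95), 0.015)
})

test_that("McNemar exact and asymptotic branches match their oracles", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_equal(mcnemar_test(10, 2)$p_value, 158 / 4096, tolerance = 1e-12)
  # symmetry and monotonicity in |b - c| at fixed b + c
  expect_equal(mcnemar_test(2, 10)$p_value, mcnemar_test(10, 2)$p_value)
  ps <- vapply(0:6, function(b) mcnemar_test(b, 12 - b)$p_value,
               numeric(1))
  expect_true(all(diff(ps) > 0))  # p rises toward b = c
  # large-sample branch against the standard continuity-corrected test
  got <- mcnemar_test(100, 50)
  oracle <- stats::mcnemar.test(matrix(c(40, 100, 50, 40), 2),
                                correct = TRUE)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_error(mcnemar_test(-1, 2), class = "invalid_config")
})

test_that("mean comparisons match a hand-computed Student t", {
  x <- c(12, 15, 11, 19, 14)
  y <- c(20, 22, 19, 25, 24)
  res <- mean_tests(x, y)
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 5))
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  # identical groups: paired t is degenerate; two-sample is t = 0 when
  # groups differ internally but not between
  expect_error(mean_tests(c(1, 1, 1, 1), c(0, 0, 0, 0), paired = TRUE),
               class = "degenerate_stat")
  same <- c(1, 2, 3, 4)
  res0 <- mean_tests(same, same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(mean_tests(rep(3, 4), rep(3, 4)), class = "degenerate_stat")
  # paired branch agrees with stats::t.test
  a <- c(30, 25, 14, 22, 40)
  b <- c(26, 27, 10, 20, 33)
  rp <- mean_tests(a, b, paired = TRUE)
  ht <- t.test(a, b, paired = TRUE)
  expect_equal(rp$p_value, ht$p.value, tolerance = 1e-12)
})
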