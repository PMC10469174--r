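# Concordant/discordant triage and the assisted-revision workflow.

test_that("concordance classification applies the inclusive 10-point rule", {
  m <- rbind(s1 = c(10, 15, 18),   # max diff 8  -> concordant
             s2 = c(10, 20, 15),   # max diff 10 -> discordant (inclusive)
             s3 = c(5, 40, 22))    # clearly discordant
  cls <- classify_concordance(panel_of(m))
  expect_equal(cls$discordant, c(FALSE, TRUE, TRUE))
  expect_equal(attr(cls, "counts"),
               c(concordant = 1L, discordant = 2L))
  # exclusive variant: a difference of exactly 10 no longer triggers
  cls2 <- classify_concordance(panel_of(m),
                               triage_config(inclusive = FALSE))
  expect_equal(cls2$discordant, c(FALSE, FALSE, TRUE))
  # slide order and rater order do not matter
  cls3 <- classify_concordance(panel_of(m[c(3, 1, 2), c(2, 3, 1)]))
  expect_equal(sum(cls3$discordant), 2L)
  expect_warning(classify_concordance(panel_of(rbind(c(10, NA, NA)))),
                 "excluded")
})

test_that("revisit flags compare each rater with the automated score", {
  expect_true(flag_revisit(15, 25))
  expect_false(flag_revisit(15, 24.9))
  expect_false(flag_revisit(42, 42))
  expect_equal(flag_revisit(c(10, 30, NA), c(25, 35, 12)),
               c(TRUE, FALSE, NA))
  expect_warning(f <- flag_revisit(15, NA), "missing automated")
  expect_false(f)
})

test_that("revision alters flagged entries only, per the reliance model", {
  set.seed(2)
  m <- cbind(A = c(10, 30, 50, 22), B = c(12, 48, 20, 22),
             DL = c(11, 40, 35, 22))
  p <- panel_of(m, automated = TRUE)
  tri <- triage_panel(p)
  # w = 0, q = 1: nothing changes
  keepers <- list(A = rater_profile("A", reliance_weight = 0,
                                    revision_prob = 1),
                  B = rater_profile("B", reliance_weight = 0,
                                    revision_prob = 1))
  out0 <- simulate_revision(p, keepers, tri, seed = 1)
  expect_identical(out0$panel$scores, p$scores)
  expect_false(any(out0$changed))
  # w = 1, q = 1: every flagged entry becomes the automated score
  pullers <- list(A = rater_profile("A", reliance_weight = 1,
                                    revision_prob = 1),
                  B = rater_profile("B", reliance_weight = 1,
                                    revision_prob = 1))
  out1 <- simulate_revision(p, pullers, tri, seed = 1)
  flagged <- which(tri$revisit, arr.ind = TRUE)
  for (k in seq_len(nrow(flagged))) {
    i <- flagged[k, 1]; j <- flagged[k, 2]
    expect_equal(out1$panel$scores[i, j], round(unname(m[i, "DL"])))
  }
  # unflagged entries are bitwise untouched
  unflagged <- !tri$revisit
  expect_identical(out1$panel$scores[, 1:2][unflagged],
                   p$scores[, 1:2][unflagged])
  # after a full pull, no revisit flags remain
  tri2 <- triage_panel(out1$panel)
  expect_false(any(tri2$revisit, na.rm = TRUE))
})

test_that("partial reliance contracts rater-automated gaps in expectation", {
  set.seed(5)
  n <- 60
  auto <- runif(n, 0, 60)
  a <- pmin(pmax(auto + rnorm(n, 8, 12), 0), 100)
  m <- cbind(A = round(a), B = round(pmin(pmax(auto + rnorm(n, -5, 10),
                                               0), 100)),
             DL = auto)
  p <- panel_of(m, automated = TRUE)
  tri <- triage_panel(p)
  prof <- list(A = rater_profile("A", reliance_weight = 0.6,
                                 revision_prob = 0.8),
               B = rater_profile("B", reliance_weight = 0.6,
                                 revision_prob = 0.8))
  gap <- function(scores) {
    mean(abs(scores[, 1:2][tri$revisit] -
               cbind(auto, auto)[tri$revisit]))
  }
  gaps <- vapply(1:100, function(s) {
    gap(simulate_revision(p, prof, tri, seed = s)$panel$scores)
  }, numeric(1))
  expect_lt(mean(gaps), gap(p$scores))
  # post-revision per-slide COV is not larger on average
  cov_pre <- cov_per_case(p)$mean
  cov_post <- mean(vapply(1:50, function(s) {
    cov_per_case(simulate_revision(p, prof, tri, seed = s)$panel)$mean
  }, numeric(1)))
  expect_lte(cov_post, cov_pre)
})

test_that("accounting reproduces strata, rates and McNemar inputs", {
  # hand-built revisit geometry: 6 slides, 3 raters
  revisit <- rbind(c(TRUE, TRUE, TRUE),
                   c(TRUE, TRUE, NA),
                   c(TRUE, FALSE, FALSE),
                   c(FALSE, FALSE, FALSE),
                   c(NA, NA, TRUE),
                   c(FALSE, NA, NA))
  colnames(revisit) <- c("A", "B", "C")
  changed <- !is.na(revisit) & revisit
  changed[1, 1] <- FALSE  # A revisited slide 1 but kept the score
  acc <- revision_accounting(revisit, changed)
  expect_identical(acc$unique_revisited, 4L)
  expect_equal(acc$unique_fraction, 4 / 6)
  expect_equal(acc$strata$n_slides[acc$strata$multiplicity == 1], 2L)
  expect_equal(acc$strata$n_slides[acc$strata$multiplicity == 2], 1L)
  expect_equal(acc$strata$n_slides[acc$strata$multiplicity == 3], 1L)
  expect_identical(sum(acc$strata$n_slides), acc$unique_revisited)
  a_row <- acc$per_rater[acc$per_rater$rater == "A", ]
  expect_identical(a_row$n_evaluated, 5L)
  expect_identical(a_row$n_revisited, 3L)
  expect_equal(a_row$change_rate, 2 / 3)
  # no flags anywhere: all zeros with rates 0
  none <- revision_accounting(revisit & FALSE)
  expect_identical(none$unique_revisited, 0L)
  expect_true(all(none$per_rater$revisit_rate == 0))
  expect_identical(nrow(none$strata), 0L)
})

test_that("before/after discordance feeds the McNemar comparison", {
  m <- cbind(A = c(10, 30, 50, 20, 5), B = c(25, 45, 20, 22, 6),
             DL = c(24, 44, 21, 21, 5))
  p <- panel_of(m, automated = TRUE)
  tri <- triage_panel(p)
  prof <- list(A = rater_profile("A", reliance_weight = 1,
                                 revision_prob = 1),
               B = rater_profile("B", reliance_weight = 1,
                                 revision_prob = 1))
  out <- simulate_revision(p, prof, tri, seed = 1)
  acc <- revision_accounting(tri, out, p)
  expect_identical(acc$before_discordant, 3L)
  expect_identical(acc$after_discordant, 0L)
  expect_identical(acc$mcnemar$b, 3L)
  expect_identical(acc$mcnemar$c, 0L)
  expect_equal(acc$mcnemar$p_value, min(1, 2 * pbinom(0, 3, 0.5)))
})
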