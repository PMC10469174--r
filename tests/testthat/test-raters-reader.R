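# Simulated pathologists and the automated reader.

test_that("a noiseless whole-slide rater reproduces the true sTIL", {
  m <- banded_map(nr = 50, nc = 90, mpp = 2)
  cells <- generate_cells(m, intensity_config(base_density = 6000,
                                              heterogeneity = 0,
                                              tumor_density = 0), seed = 4)
  truth <- true_stil(m, cells)$true_stil
  expect_equal(simulate_rater(m, cells, exact_rater(), seed = 1),
               round(truth))
  # additive bias shifts the (rounded) estimate by the stated points
  biased <- exact_rater("B")
  biased$additive_bias <- 5
  expect_equal(simulate_rater(m, cells, biased, seed = 1),
               round(truth + 5))
  # multiplicative bias scales it
  scaled <- exact_rater("C")
  scaled$multiplicative_bias <- 0.5
  expect_equal(simulate_rater(m, cells, scaled, seed = 1),
               round(truth * 0.5))
  no_stroma <- tissue_map(matrix(1L, 6, 6), 2)
  expect_error(simulate_rater(no_stroma, cells, exact_rater(), seed = 1),
               class = "undefined_score")
})

test_that("spatial heterogeneity inflates field-sampling dispersion", {
  m <- stroma_block_map(1, mpp = 4)
  prof <- rater_profile("H", k_fields = 2, field_size = 200,
                        noise_sd = 0, rounding_grain = 1)
  score_sd <- function(het) {
    cfg <- intensity_config(base_density = 6000, heterogeneity = het,
                            field_correlation_length = 150,
                            tumor_density = 0)
    sd(vapply(1:120, function(s) {
      cells <- generate_cells(m, cfg, seed = s)
      simulate_rater(m, cells, prof, seed = 1000 + s)
    }, numeric(1)))
  }
  expect_gt(score_sd(2), score_sd(0))
})

test_that("a perfect reader reproduces the truth exactly", {
  m <- banded_map(nr = 60, nc = 90)
  cells <- generate_cells(m, intensity_config(base_density = 5000,
                                              heterogeneity = 1), seed = 8)
  perfect <- reader_error_profile(lymphoid_recall = 1,
                                  false_positive_rate = 0,
                                  mask_iou_target = 1)
  dl <- simulate_dl_reader(m, cells, perfect, seed = 3)
  expect_identical(dl$map$labels, m$labels)
  expect_equal(dl$realized_iou, 1)
  expect_identical(nrow(dl$cells), nrow(cells))
  expect_equal(dl$score, score_slide(cells, m)$score)
})

test_that("lymphoid thinning halves the expected detected count", {
  m <- banded_map(nr = 50, nc = 75)
  cells <- generate_cells(m, intensity_config(base_density = 6000,
                                              heterogeneity = 0,
                                              tumor_density = 0), seed = 12)
  n_true <- sum(cells$cell_class == "lymphoid")
  half <- reader_error_profile(lymphoid_recall = 0.5,
                               false_positive_rate = 0,
                               mask_iou_target = 1)
  detected <- vapply(1:200, function(s) {
    simulate_dl_reader(m, cells, half, seed = s)$n_detected_lymphoid
  }, numeric(1))
  p <- mean(detected) / n_true
  se <- sqrt(0.25 / (200 * n_true))
  expect_lt(abs(p - 0.5), 4 * se)
  # and the mean score is near half the perfect-profile score
  perfect_score <- score_slide(cells, m)$score
  scores <- vapply(1:50, function(s) {
    simulate_dl_reader(m, cells, half, seed = s)$score
  }, numeric(1))
  expect_lt(abs(mean(scores) / perfect_score - 0.5), 0.05)
})

test_that("stroma-mask degradation hits its IoU target", {
  m <- generate_tissue_map(1024, 1024, 2, 0.4, 0.35, seed = 21)
  cells <- generate_cells(m, intensity_config(base_density = 4000),
                          seed = 22)
  dl <- simulate_dl_reader(m, cells,
                           reader_error_profile(mask_iou_target = 0.666),
                           seed = 23)
  expect_gt(dl$realized_iou, 0.616)
  expect_lt(dl$realized_iou, 0.716)
  # independent recomputation through the metrics operation
  met <- detection_metrics(cells, dl$cells, truth_map = m,
                           degraded_map = dl$map)
  expect_equal(unname(met$iou[["stroma"]]), dl$realized_iou)
})

test_that("detection F1 follows the closed form under greedy matching", {
  m <- banded_map()
  truth <- cells_at(m, rows = rep(1:10, each = 1), cols = 1:10)
  # detect exactly half of them
  det <- truth[1:5, ]
  class(det) <- class(truth)
  f1 <- detection_metrics(truth, det)$f1
  lym <- f1[f1$cell_class == "lymphoid", ]
  expect_equal(lym$precision, 1)
  expect_equal(lym$recall, 0.5)
  expect_equal(lym$f1, 2 / 3)

  ident <- detection_metrics(truth, truth, truth_map = m,
                             degraded_map = m)
  expect_equal(ident$f1$f1, c(1, 1))
  expect_true(all(ident$iou == 1))

  # empty truth and empty detection: F1 = 1 by convention
  empty <- truth[0, ]
  class(empty) <- class(truth)
  expect_equal(detection_metrics(empty, empty)$f1$f1, c(1, 1))
  # spurious detections against empty truth: F1 = 0
  expect_equal(
    detection_metrics(empty, det)$f1$f1[1], 0)

  # disjoint masks give IoU 0
  a <- tissue_map(matrix(c(2L, 0L), 2, 2), 1)
  b <- tissue_map(matrix(c(0L, 2L), 2, 2), 1)
  expect_equal(unname(detection_metrics(empty, empty, truth_map = a,
                                        degraded_map = b)$iou[["stroma"]]),
               0)
})

test_that("greedy matching is one-to-one within the radius", {
  m <- banded_map()
  truth <- cells_at(m, rows = c(5, 5), cols = c(5, 6))
  # one detection equidistant-ish between two truths: only one match
  det <- cells_at(m, rows = 5, cols = 5)
  f1 <- detection_metrics(truth, det, match_radius_um = 6)$f1
  lym <- f1[f1$cell_class == "lymphoid", ]
  expect_equal(lym$tp, 1)
  # far detections never match
  far <- cells_at(m, rows = 30, cols = 5)
  f0 <- detection_metrics(truth, far, match_radius_um = 6)$f1
  expect_equal(f0[f0$cell_class == "lymphoid", "tp"], 0)
})
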