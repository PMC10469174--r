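# Simulated pathologist raters and the error-prone automated reader.

#' Rater profile
#'
#' Generative parameters for a simulated pathologist who estimates the sTIL
#' percentage visually: a handful of fields are sampled, local coverage is
#' estimated with multiplicative lognormal noise, and the average is
#' distorted by a multiplicative and an additive bias, rounded to a
#' reporting grain and clamped to \[0, 100\]. `reliance_weight` and
#' `revision_prob` govern the rater's behavior when a slide is returned
#' with the automated score (see [simulate_revision()]).
#'
#' @param rater_id identifier.
#' @param k_fields number of visual fields sampled (>= 1).
#' @param field_size field edge length in microns.
#' @param additive_bias percentage points added to the final estimate.
#' @param multiplicative_bias unitless factor on the averaged estimate.
#' @param noise_sd lognormal sigma of per-field multiplicative noise
#'   (mean-one parameterization, so zero bias means unbiased in
#'   expectation).
#' @param rounding_grain reporting grain in percentage points (>= 1).
#' @param reliance_weight pull toward the automated score on revision,
#'   in \[0, 1\].
#' @param revision_prob probability of actually rescoring a revisited
#'   slide, in \[0, 1\].
#' @return a `rater_profile` list.
#' @export
rater_profile <- function(rater_id, k_fields = 5, field_size = 500,
                          additive_bias = 0, multiplicative_bias = 1,
                          noise_sd = 0.3, rounding_grain = 5,
                          reliance_weight = 0.7, revision_prob = 0.8) {
  if (k_fields < 1 || rounding_grain < 1 ||
      reliance_weight < 0 || reliance_weight > 1 ||
      revision_prob < 0 || revision_prob > 1 || noise_sd < 0) {
    stil_stop("invalid rater profile", "invalid_config")
  }
  structure(list(rater_id = as.character(rater_id),
                 k_fields = as.integer(k_fields), field_size = field_size,
                 additive_bias = additive_bias,
                 multiplicative_bias = multiplicative_bias,
                 noise_sd = noise_sd,
                 rounding_grain = rounding_grain,
                 reliance_weight = reliance_weight,
                 revision_prob = revision_prob),
            class = "rater_profile")
}

#' Default four-rater panel
#'
#' Profiles loosely emulating four readers with distinct calibration:
#' one systematic under-scorer with high revision compliance, two
#' over-scorers with moderate compliance, and one near-unbiased,
#' conservative reader. All share a 5-point reporting grain.
#'
#' @return named list of `rater_profile`s (A-D).
#' @export
default_rater_profiles <- function() {
  list(
    A = rater_profile("A", k_fields = 4, multiplicative_bias = 0.75,
                      noise_sd = 0.30, reliance_weight = 0.80,
                      revision_prob = 0.93),
    B = rater_profile("B", k_fields = 4, multiplicative_bias = 1.20,
                      noise_sd = 0.35, reliance_weight = 0.60,
                      revision_prob = 0.70),
    C = rater_profile("C", k_fields = 4, multiplicative_bias = 1.12,
                      noise_sd = 0.40, reliance_weight = 0.70,
                      revision_prob = 0.83),
    D = rater_profile("D", k_fields = 5, multiplicative_bias = 1.00,
                      noise_sd = 0.25, reliance_weight = 0.60,
                      revision_prob = 0.60))
}

#' Simulate a pathologist's visual sTIL estimate
#'
#' Samples `k_fields` square windows centered on uniformly chosen stroma
#' pixels, estimates the geometric stromal coverage within each window,
#' multiplies by mean-one lognormal noise, averages the fields, applies the
#' multiplicative then additive bias, rounds to the reporting grain and
#' clamps to \[0, 100\] last. With all error parameters zero and a field
#' covering the whole slide, the result is the true sTIL rounded to the
#' grain.
#'
#' @param map a `tissue_map`.
#' @param cells a `cell_table`.
#' @param profile a `rater_profile`.
#' @param seed integer seed.
#' @return sTIL percentage (scalar).
#' @export
simulate_rater <- function(map, cells, profile, seed = NULL) {
  stopifnot(inherits(profile, "rater_profile"))
  nr <- nrow(map$labels)
  nc <- ncol(map$labels)
  stroma_idx <- which(map$labels == TISSUE_CODES[["stroma"]])
  if (length(stroma_idx) == 0L) {
    stil_stop("sTIL undefined: slide has no cancer stroma",
              "undefined_score")
  }
  lym <- cells[cells$cell_class == "lymphoid", , drop = FALSE]
  lrow <- lcol <- integer(0)
  if (nrow(lym)) {
    idx <- cell_pixel_index(lym, map)
    on_stroma <- map$labels[idx] == TISSUE_CODES[["stroma"]]
    lrow <- ((idx[on_stroma] - 1L) %% nr) + 1L
    lcol <- ((idx[on_stroma] - 1L) %/% nr) + 1L
  }
  stroma <- map$labels == TISSUE_CODES[["stroma"]]
  fs_px <- max(1L, as.integer(round(profile$field_size / map$mpp)))
  half <- fs_px %/% 2L
  with_seed(seed, {
    centers <- stroma_idx[sample.int(length(stroma_idx), profile$k_fields,
                                     replace = TRUE)]
    est <- numeric(profile$k_fields)
    for (f in seq_len(profile$k_fields)) {
      cr <- ((centers[f] - 1L) %% nr) + 1L
      cc <- ((centers[f] - 1L) %/% nr) + 1L
      r1 <- max(1L, cr - half); r2 <- min(nr, cr - half + fs_px - 1L)
      c1 <- max(1L, cc - half); c2 <- min(nc, cc - half + fs_px - 1L)
      a <- sum(stroma[r1:r2, c1:c2]) * map$mpp^2
      n <- sum(lrow >= r1 & lrow <= r2 & lcol >= c1 & lcol <= c2)
      cov_f <- 100 * pi * LYMPHOCYTE_RADIUS_UM^2 * n / a
      noise <- if (profile$noise_sd > 0) {
        stats::rlnorm(1, meanlog = -profile$noise_sd^2 / 2,
                      sdlog = profile$noise_sd)
      } else 1
      est[f] <- cov_f * noise
    }
    val <- mean(est) * profile$multiplicative_bias + profile$additive_bias
    val <- profile$rounding_grain * round(val / profile$rounding_grain)
    min(max(val, 0), 100)
  })
}

#' Automated-reader error profile
#'
#' @param lymphoid_recall probability a true lymphoid cell is detected.
#' @param false_positive_rate spurious lymphoid detections per mm^2 of
#'   stroma. The default pairs with `lymphoid_recall` so that, at the
#'   cohort-mean lymphoid density of about 8000 per mm^2, precision is
#'   close to recall and the lymphocyte F1 sits near 0.79.
#' @param mask_iou_target desired IoU between the degraded and true stroma
#'   mask, in (0, 1]. Defaults anchored at the deployed model's breast
#'   performance (lymphocyte F1 about 79%, stroma IoU about 0.666).
#' @param perturbation_scale correlation length (um) of the spatial
#'   perturbation applied to the stroma mask.
#' @return a `reader_error_profile` list.
#' @export
reader_error_profile <- function(lymphoid_recall = 0.79,
                                 false_positive_rate = 1300,
                                 mask_iou_target = 0.666,
                                 perturbation_scale = 50) {
  if (lymphoid_recall < 0 || lymphoid_recall > 1 ||
      false_positive_rate < 0 ||
      mask_iou_target <= 0 || mask_iou_target > 1 ||
      perturbation_scale < 0) {
    stil_stop("invalid reader error profile", "invalid_config")
  }
  structure(list(lymphoid_recall = lymphoid_recall,
                 false_positive_rate = false_positive_rate,
                 mask_iou_target = mask_iou_target,
                 perturbation_scale = perturbation_scale),
            class = "reader_error_profile")
}

# Degrade the stroma mask toward a target IoU by swapping equal numbers of
# pixels in and out, chosen by a smooth random field so that errors form
# spatial blobs. Removing and adding a fraction a of the stroma pixel count
# gives IoU (1 - a) / (1 + a); a is solved from the target.
degrade_stroma_mask <- function(map, iou_target, perturbation_scale) {
  labels <- map$labels
  stroma_idx <- which(labels == TISSUE_CODES[["stroma"]])
  s <- length(stroma_idx)
  if (s == 0L || iou_target >= 1) {
    return(list(map = map, realized_iou = 1))
  }
  nr <- nrow(labels)
  u <- smooth_gaussian_field(nr, ncol(labels),
                             max(perturbation_scale, 1e-9) / map$mpp)
  a <- (1 - iou_target) / (1 + iou_target)
  n_swap <- round(a * s)
  if (n_swap > 0) {
    drop_idx <- stroma_idx[order(u[stroma_idx])[seq_len(min(n_swap, s))]]
    other_idx <- which(labels != TISSUE_CODES[["stroma"]])
    n_add <- min(n_swap, length(other_idx))
    if (n_add < n_swap) {
      warning("mask IoU target unattainable: not enough non-stroma pixels")
    }
    add_idx <- if (n_add > 0) {
      other_idx[order(u[other_idx], decreasing = TRUE)[seq_len(n_add)]]
    } else integer(0)
    # misread stroma is typically confused with cancer area
    labels[drop_idx] <- TISSUE_CODES[["cancer"]]
    labels[add_idx] <- TISSUE_CODES[["stroma"]]
  }
  new_map <- tissue_map(labels, map$mpp, map$slide_id)
  truth <- map$labels == TISSUE_CODES[["stroma"]]
  degr <- labels == TISSUE_CODES[["stroma"]]
  realized <- sum(truth & degr) / sum(truth | degr)
  list(map = new_map, realized_iou = realized)
}

#' Simulate the automated (deep-learning style) reader
#'
#' Each true lymphoid cell is retained with probability `lymphoid_recall`;
#' spurious lymphoid detections are added as a Poisson process on the
#' degraded stroma; the stroma mask is perturbed by spatially correlated
#' pixel swaps tuned so the realized IoU matches `mask_iou_target` (a
#' warning reports the realized value when the target is unattainable).
#' The score is then computed by [score_slide()] on the degraded outputs.
#'
#' @param map true `tissue_map`.
#' @param cells true `cell_table`.
#' @param err a `reader_error_profile`.
#' @param cfg a `scoring_config`.
#' @param seed integer seed.
#' @return a `dl_read` list: cells (detected), map (degraded), score,
#'   realized_iou, n_true_lymphoid, n_detected_lymphoid.
#' @export
simulate_dl_reader <- function(map, cells, err = reader_error_profile(),
                               cfg = scoring_config(), seed = NULL) {
  stopifnot(inherits(err, "reader_error_profile"))
  with_seed(seed, {
    deg <- degrade_stroma_mask(map, err$mask_iou_target,
                               err$perturbation_scale)
    lym <- cells[cells$cell_class == "lymphoid", , drop = FALSE]
    keep <- if (nrow(lym)) {
      stats::runif(nrow(lym)) < err$lymphoid_recall
    } else logical(0)
    det_lym <- lym[keep, , drop = FALSE]
    # false positives on the degraded stroma (what the reader believes)
    fp <- data.frame(x_um = numeric(), y_um = numeric())
    area_mm2 <- stroma_area(deg$map) / 1e6
    if (err$false_positive_rate > 0 && area_mm2 > 0) {
      n_fp <- stats::rpois(1, err$false_positive_rate * area_mm2)
      if (n_fp > 0) {
        s_idx <- which(deg$map$labels == TISSUE_CODES[["stroma"]])
        pos <- s_idx[sample.int(length(s_idx), n_fp, replace = TRUE)]
        nr <- nrow(map$labels)
        row <- ((pos - 1L) %% nr) + 1L
        col <- ((pos - 1L) %/% nr) + 1L
        fp <- data.frame(x_um = (col - 1 + stats::runif(n_fp)) * map$mpp,
                         y_um = (row - 1 + stats::runif(n_fp)) * map$mpp)
      }
    }
    tum <- cells[cells$cell_class == "tumor", , drop = FALSE]
    detected <- cell_table(
      map$slide_id,
      c(det_lym$x_um, fp$x_um, tum$x_um),
      c(det_lym$y_um, fp$y_um, tum$y_um),
      c(rep("lymphoid", nrow(det_lym) + nrow(fp)),
        rep("tumor", nrow(tum))))
    sc <- score_slide(detected, deg$map, cfg)
    structure(list(cells = detected, map = deg$map, score = sc$score,
                   realized_iou = deg$realized_iou,
                   n_true_lymphoid = nrow(lym),
                   n_detected_lymphoid = nrow(det_lym) + nrow(fp)),
              class = "dl_read")
  })
}

#' Detection and segmentation quality metrics
#'
#' Point detections are matched to ground truth by greedy nearest-neighbor
#' one-to-one matching within `match_radius` (default 6 um), per cell
#' class; F1 is the harmonic mean of the resulting precision and recall.
#' An empty truth matched against an empty detection has F1 = 1 by
#' convention. When the two tissue maps are supplied, per-class IoU
#' (|intersection| / |union| of label masks) is also reported.
#'
#' @param truth,detected `cell_table`s for the same slide.
#' @param match_radius_um matching radius in microns.
#' @param truth_map,degraded_map optional `tissue_map`s for IoU.
#' @return list with `f1` (data.frame per cell class) and `iou` (named
#'   vector per tissue class, or NULL).
#' @export
detection_metrics <- function(truth, detected, match_radius_um = 6,
                              truth_map = NULL, degraded_map = NULL) {
  classes <- CELL_CLASSES
  rows <- lapply(classes, function(cl) {
    tt <- truth[truth$cell_class == cl, , drop = FALSE]
    dd <- detected[detected$cell_class == cl, , drop = FALSE]
    tp <- greedy_match_count(tt$x_um, tt$y_um, dd$x_um, dd$y_um,
                             match_radius_um)
    nt <- nrow(tt); nd <- nrow(dd)
    if (nt == 0 && nd == 0) {
      prec <- rec <- f1 <- 1  # documented convention
    } else {
      prec <- if (nd > 0) tp / nd else 0
      rec <- if (nt > 0) tp / nt else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }
    data.frame(cell_class = cl, n_truth = nt, n_detected = nd, tp = tp,
               precision = prec, recall = rec, f1 = f1)
  })
  iou <- NULL
  if (!is.null(truth_map) && !is.null(degraded_map)) {
    iou <- vapply(TISSUE_CODES, function(code) {
      a <- truth_map$labels == code
      b <- degraded_map$labels == code
      u <- sum(a | b)
      if (u == 0) 1 else sum(a & b) / u
    }, numeric(1))
  }
  list(f1 = do.call(rbind, rows), iou = iou)
}

# Greedy one-to-one matching: all candidate pairs within radius are found
# via spatial binning, sorted by distance, and accepted greedily. Returns
# the number of matched (true positive) pairs.
greedy_match_count <- function(tx, ty, dx, dy, radius) {
  nt <- length(tx); nd <- length(dx)
  if (nt == 0L || nd == 0L) return(0L)
  key <- function(x, y) paste(floor(x / radius), floor(y / radius))
  bins <- split(seq_len(nd), key(dx, dy))
  pt <- vector("list", nt)
  for (i in seq_len(nt)) {
    kx <- floor(tx[i] / radius); ky <- floor(ty[i] / radius)
    cand <- unlist(bins[paste(rep(kx + (-1:1), each = 3),
                              rep(ky + (-1:1), 3))], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- (dx[cand] - tx[i])^2 + (dy[cand] - ty[i])^2
    ok <- d2 <= radius^2
    if (any(ok)) {
      pt[[i]] <- cbind(i, cand[ok], d2[ok])
    }
  }
  pairs <- do.call(rbind, pt)
  if (is.null(pairs) || nrow(pairs) == 0L) return(0L)
  pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- used_d[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}
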