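# sTIL scoring: normalized lymphoid count over cancer-stroma area, grid
# extraction, and calibration of the proportionality constant alpha.

#' Scoring configuration
#'
#' The sTIL score is `alpha * lymphoid_count / (stroma_area / area_unit)`.
#' The automated reader reports lymphoid cells as points, not areas, so a
#' proportionality constant is needed to convert a count per unit stroma
#' area into an occupied-area percentage. With `area_unit = 400` um^2 the
#' geometric coverage of 3-um-radius lymphocyte discs corresponds to a
#' multiplier of `100 * pi * 9 / 400 = 7.068`, which is why alpha near 7
#' is the natural choice; alpha itself is fixed by calibration against
#' pathologist panels (see [calibrate_alpha()]).
#'
#' @param alpha proportionality constant (> 0, default 7.0).
#' @param area_unit um^2 per area unit in the denominator (default 400).
#' @param clamp clamp scores into \[0, 100\] (default TRUE). Calibration
#'   works on raw (unclamped) values.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(alpha = 7.0, area_unit = 400, clamp = TRUE) {
  if (alpha <= 0 || area_unit <= 0) {
    stil_stop("alpha and area_unit must be positive", "invalid_config")
  }
  structure(list(alpha = alpha, area_unit = area_unit, clamp = isTRUE(clamp)),
            class = "scoring_config")
}

#' Compute the sTIL score from a lymphoid count and stroma area
#'
#' @param lymphoid_count non-negative count(s).
#' @param stroma_area_um2 stroma area(s) in um^2, strictly positive.
#' @param cfg a `scoring_config`.
#' @return score(s) in percent; clamped to \[0, 100\] when `cfg$clamp`.
#' @export
stil_score <- function(lymphoid_count, stroma_area_um2,
                       cfg = scoring_config()) {
  if (any(lymphoid_count < 0)) {
    stil_stop("lymphoid_count must be >= 0", "invalid_config")
  }
  if (any(!is.finite(stroma_area_um2)) || any(stroma_area_um2 <= 0)) {
    stil_stop("sTIL undefined: stroma area must be positive",
              "undefined_score")
  }
  raw <- cfg$alpha * lymphoid_count / (stroma_area_um2 / cfg$area_unit)
  if (cfg$clamp) pmin(pmax(raw, 0), 100) else raw
}

#' Score a whole slide
#'
#' Counts lymphoid cells lying on stroma-labeled pixels only, and divides by
#' the total stroma area. Optionally returns a diagnostic table over a
#' non-overlapping square tiling.
#'
#' @param cells a `cell_table`.
#' @param map a `tissue_map`.
#' @param cfg a `scoring_config`.
#' @param tile_px optional tile edge in pixels for the per-tile table.
#' @return a `stil_slide_score` list with fields score, raw,
#'   lymphoid_in_stroma, stroma_area_um2, and (optionally) tiles.
#' @export
score_slide <- function(cells, map, cfg = scoring_config(), tile_px = NULL) {
  n <- count_lymphoid_in_stroma(cells, map)
  area <- stroma_area(map)
  if (area <= 0) {
    stil_stop("sTIL undefined: slide has no cancer stroma",
              "undefined_score")
  }
  raw <- cfg$alpha * n / (area / cfg$area_unit)
  tiles <- NULL
  if (!is.null(tile_px)) {
    tiles <- tile_table(cells, map, cfg, as.integer(tile_px))
  }
  structure(list(score = if (cfg$clamp) min(max(raw, 0), 100) else raw,
                 raw = raw, lymphoid_in_stroma = n,
                 stroma_area_um2 = area, tiles = tiles),
            class = "stil_slide_score")
}

#' @export
print.stil_slide_score <- function(x, ...) {
  cat(sprintf("sTIL %.2f%% (%d lymphoid cells in %.3g mm^2 stroma)\n",
              x$score, x$lymphoid_in_stroma, x$stroma_area_um2 / 1e6))
  invisible(x)
}

# Non-overlapping tiling diagnostics: counts, areas and scores per tile.
tile_table <- function(cells, map, cfg, tile_px) {
  nr <- nrow(map$labels)
  nc <- ncol(map$labels)
  lym <- cells[cells$cell_class == "lymphoid", , drop = FALSE]
  idx <- if (nrow(lym)) cell_pixel_index(lym, map) else integer()
  on_stroma <- map$labels[idx] == TISSUE_CODES[["stroma"]]
  row <- ((idx[on_stroma] - 1L) %% nr) + 1L
  col <- ((idx[on_stroma] - 1L) %/% nr) + 1L
  tr <- (row - 1L) %/% tile_px
  tc <- (col - 1L) %/% tile_px
  ntr <- as.integer(ceiling(nr / tile_px))
  ntc <- as.integer(ceiling(nc / tile_px))
  counts <- matrix(0L, ntr, ntc)
  if (length(tr)) {
    tab <- table(factor(tr, levels = 0:(ntr - 1)),
                 factor(tc, levels = 0:(ntc - 1)))
    counts <- matrix(as.integer(tab), ntr, ntc)
  }
  stroma <- (map$labels == TISSUE_CODES[["stroma"]]) + 0
  areas <- matrix(0, ntr, ntc)
  for (i in seq_len(ntr)) {
    for (j in seq_len(ntc)) {
      r <- ((i - 1L) * tile_px + 1L):min(i * tile_px, nr)
      cI <- ((j - 1L) * tile_px + 1L):min(j * tile_px, nc)
      areas[i, j] <- sum(stroma[r, cI]) * map$mpp^2
    }
  }
  grid <- expand.grid(tile_row = seq_len(ntr), tile_col = seq_len(ntc))
  out <- data.frame(grid,
                    lymphoid_in_stroma = as.vector(counts),
                    stroma_area_um2 = as.vector(areas))
  out$score <- ifelse(out$stroma_area_um2 > 0,
                      cfg$alpha * out$lymphoid_in_stroma /
                        (out$stroma_area_um2 / cfg$area_unit), NA_real_)
  if (cfg$clamp) out$score <- pmin(pmax(out$score, 0), 100)
  out
}

#' Randomly crop square grid patches from a slide
#'
#' Mirrors the patch-level protocol used to calibrate alpha: square windows
#' are cropped uniformly at random; each carries its own lymphoid-in-stroma
#' count and stroma area. Patches without any stroma are flagged as
#' unscorable rather than scored zero.
#'
#' @param map a `tissue_map`.
#' @param cells a `cell_table`.
#' @param n_grids number of crops.
#' @param grid_px window edge length in pixels (must fit in the slide).
#' @param seed integer seed.
#' @return data.frame with columns patch_id, x0_um, y0_um, size_um,
#'   lymphoid_in_stroma, stroma_area_um2, scorable.
#' @export
extract_grids <- function(map, cells, n_grids, grid_px, seed = NULL) {
  nr <- nrow(map$labels)
  nc <- ncol(map$labels)
  grid_px <- as.integer(grid_px)
  if (grid_px < 1L || grid_px > nr || grid_px > nc) {
    stil_stop("grid does not fit in the slide", "invalid_config")
  }
  stroma_sat <- summed_area_table(
    (map$labels == TISSUE_CODES[["stroma"]]) + 0)
  lym <- cells[cells$cell_class == "lymphoid", , drop = FALSE]
  pts <- matrix(0, nr, nc)
  if (nrow(lym)) {
    idx <- cell_pixel_index(lym, map)
    on_stroma <- map$labels[idx] == TISSUE_CODES[["stroma"]]
    tab <- tabulate(idx[on_stroma], nbins = nr * nc)
    pts <- matrix(tab, nr, nc)
  }
  pts_sat <- summed_area_table(pts)
  with_seed(seed, {
    r1 <- sample.int(nr - grid_px + 1L, n_grids, replace = TRUE)
    c1 <- sample.int(nc - grid_px + 1L, n_grids, replace = TRUE)
    r2 <- r1 + grid_px - 1L
    c2 <- c1 + grid_px - 1L
    area <- sat_sum(stroma_sat, r1, r2, c1, c2) * map$mpp^2
    count <- sat_sum(pts_sat, r1, r2, c1, c2)
    data.frame(patch_id = sprintf("%s_g%04d", map$slide_id,
                                  seq_len(n_grids)),
               x0_um = (c1 - 1) * map$mpp, y0_um = (r1 - 1) * map$mpp,
               size_um = grid_px * map$mpp,
               lymphoid_in_stroma = as.integer(round(count)),
               stroma_area_um2 = area,
               scorable = area > 0)
  })
}

#' Calibrate the proportionality constant alpha against a rater panel
#'
#' For each candidate alpha, computes Lin's concordance correlation
#' coefficient between raw Eq.-style grid scores
#' `alpha * count / (area / area_unit)` and the rater-panel mean, overall
#' and restricted to low-score ranges (panel mean < 10, < 15, < 20). The
#' candidate maximizing overall CCC is selected; ties are broken toward the
#' better low-range (< 20) CCC and then toward the smaller alpha, which
#' formalizes the preference for a balanced constant across the score range.
#'
#' @param grid_scores matrix of rater scores (grids x raters) or a vector of
#'   panel means; grids scored by all raters are required.
#' @param counts lymphoid-in-stroma counts per grid.
#' @param areas stroma areas per grid (um^2).
#' @param candidates candidate alpha values (default `c(6.5, 7.0, 7.5)`).
#' @param cfg a `scoring_config`; only `area_unit` is used (raw scores).
#' @return an `alpha_calibration` list with candidates, ccc_overall,
#'   ccc_by_range, selected_alpha, n_grids.
#' @export
calibrate_alpha <- function(grid_scores, counts, areas,
                            candidates = c(6.5, 7.0, 7.5),
                            cfg = scoring_config()) {
  if (length(candidates) < 1L) {
    stil_stop("at least one candidate alpha required", "invalid_config")
  }
  scores <- if (is.matrix(grid_scores)) rowMeans(grid_scores) else
    as.numeric(grid_scores)
  keep <- is.finite(scores) & is.finite(counts) & is.finite(areas) & areas > 0
  scores <- scores[keep]
  counts <- counts[keep]
  areas <- areas[keep]
  if (length(scores) < 2L) {
    stil_stop("need at least 2 scorable grids", "invalid_config")
  }
  if (stats::sd(scores) == 0) {
    stil_stop("degenerate calibration: rater panel scores are constant",
              "degenerate_stat")
  }
  ranges <- list(`<10` = scores < 10, `<15` = scores < 15,
                 `<20` = scores < 20, all = rep(TRUE, length(scores)))
  ccc_overall <- numeric(length(candidates))
  ccc_by_range <- matrix(NA_real_, length(candidates), length(ranges),
                         dimnames = list(as.character(candidates),
                                         names(ranges)))
  for (i in seq_along(candidates)) {
    eq <- candidates[i] * counts / (areas / cfg$area_unit)
    ccc_overall[i] <- lins_ccc(eq, scores)$estimate
    for (j in seq_along(ranges)) {
      sel <- ranges[[j]]
      if (sum(sel) >= 3 && stats::sd(scores[sel]) > 0 &&
          stats::sd(eq[sel]) > 0) {
        ccc_by_range[i, j] <- lins_ccc(eq[sel], scores[sel])$estimate
      }
    }
  }
  # selection: overall CCC, then low-range (<20) CCC, then smaller alpha
  ord <- order(-ccc_overall,
               -ifelse(is.na(ccc_by_range[, "<20"]), -Inf,
                       ccc_by_range[, "<20"]),
               candidates)
  structure(list(candidates = candidates, ccc_overall = ccc_overall,
                 ccc_by_range = ccc_by_range,
                 selected_alpha = candidates[ord[1L]],
                 n_grids = length(scores)),
            class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("alpha calibration on %d grids\n", x$n_grids))
  for (i in seq_along(x$candidates)) {
    cat(sprintf("  alpha %.1f: CCC %.4f (overall), %.4f (<20)\n",
                x$candidates[i], x$ccc_overall[i], x$ccc_by_range[i, "<20"]))
  }
  cat(sprintf("  selected alpha: %.1f\n", x$selected_alpha))
  invisible(x)
}
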