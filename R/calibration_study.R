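# Simulation harness for the alpha calibration: synthetic grids scored by
# unbiased geometric raters.

#' One replicate of the alpha calibration on synthetic grids
#'
#' Generates a handful of synthetic slides with per-slide mean sTIL drawn
#' from a Beta model (cohort mean 22.7%, SD 19.3%), crops `n_grids` square
#' windows uniformly at random, has `n_raters` simulated unbiased raters
#' score each scorable grid as its true geometric stromal coverage times
#' mean-one lognormal noise, and runs [calibrate_alpha()] over the
#' candidate constants. The geometric coverage multiplier under the
#' 400 um^2 area unit is 100 * pi * 9 / 400 = 7.068, so unbiased raters
#' should select the candidate nearest that value.
#'
#' @param seed integer seed for the replicate.
#' @param n_grids number of grid crops (default 249).
#' @param grid_px grid edge in pixels (default 1024).
#' @param n_slides slides to crop from (default 4).
#' @param slide_px slide edge in pixels (default 1280).
#' @param mpp microns per pixel (default 2).
#' @param n_raters number of simulated raters (default 3).
#' @param noise_sd lognormal sigma of rater noise (default 0.1).
#' @param candidates candidate alpha values.
#' @param cfg a `scoring_config` (area unit).
#' @return an `alpha_calibration`.
#' @export
simulate_grid_calibration <- function(seed, n_grids = 249, grid_px = 1024,
                                      n_slides = 4, slide_px = 1280,
                                      mpp = 2, n_raters = 3,
                                      noise_sd = 0.1,
                                      candidates = c(6.5, 7.0, 7.5),
                                      cfg = scoring_config()) {
  seeds <- sub_seeds(seed, 2L * n_slides + 2L)
  slide_um <- slide_px * mpp
  per_slide <- diff(round(seq(0, n_grids, length.out = n_slides + 1)))
  stils <- with_seed(seeds[1L], {
    s <- sample_slide_truths(n_slides, 22.7, 19.3)$true_stil
    pmin(pmax(s, 1), 85)
  })
  grids <- NULL
  for (i in seq_len(n_slides)) {
    map <- generate_tissue_map(slide_um, slide_um, mpp,
                               stroma_fraction = 0.45,
                               cancer_fraction = 0.3,
                               seed = seeds[2L * i],
                               correlation_um = slide_um / 8,
                               slide_id = sprintf("cal_%02d", i))
    icfg <- intensity_config(base_density = stil_to_density(stils[i]),
                             heterogeneity = 1,
                             field_correlation_length = 300,
                             tumor_density = 0)
    cells <- generate_cells(map, icfg, seed = seeds[2L * i + 1L])
    g <- extract_grids(map, cells, per_slide[i], grid_px,
                       seed = seeds[2L * i] + 1L)
    grids <- rbind(grids, g)
  }
  grids <- grids[grids$scorable, , drop = FALSE]
  coverage <- 100 * pi * LYMPHOCYTE_RADIUS_UM^2 *
    grids$lymphoid_in_stroma / grids$stroma_area_um2
  rater_scores <- with_seed(seeds[2L * n_slides + 2L], {
    matrix(coverage * stats::rlnorm(length(coverage) * n_raters,
                                    meanlog = -noise_sd^2 / 2,
                                    sdlog = noise_sd),
           nrow = length(coverage), ncol = n_raters)
  })
  calibrate_alpha(rater_scores, grids$lymphoid_in_stroma,
                  grids$stroma_area_um2, candidates, cfg)
}

#' Replicated alpha calibration with majority vote
#'
#' Runs [simulate_grid_calibration()] over `n_replicates` seeds derived
#' from the master seed and reports the selection frequencies and the
#' modal selected alpha.
#'
#' @param seed master seed.
#' @param n_replicates number of replicates (default 100).
#' @param ... passed to [simulate_grid_calibration()].
#' @return list: selections (vector), freq (table), modal_alpha,
#'   n_replicates.
#' @export
replicate_grid_calibration <- function(seed, n_replicates = 100, ...) {
  seeds <- sub_seeds(seed, n_replicates)
  selections <- vapply(seeds, function(s) {
    simulate_grid_calibration(s, ...)$selected_alpha
  }, numeric(1))
  freq <- table(selections)
  modal <- as.numeric(names(freq)[which.max(freq)])
  list(selections = selections, freq = freq, modal_alpha = modal,
       n_replicates = n_replicates)
}
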