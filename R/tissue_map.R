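# Tissue label rasters: 0 = background, 1 = cancer area, 2 = cancer stroma.

TISSUE_CODES <- c(background = 0L, cancer = 1L, stroma = 2L)

#' Construct a tissue map
#'
#' A tissue map is an integer label raster with a physical scale. Label codes
#' are 0 (background), 1 (cancer area) and 2 (cancer stroma). Rasters are
#' indexed (row, col) = (y, x) with the origin at the top-left and y
#' increasing downward; a point at (x, y) microns falls in pixel
#' (floor(y/mpp) + 1, floor(x/mpp) + 1).
#'
#' @param labels integer matrix with values in {0, 1, 2}.
#' @param mpp microns per pixel (> 0).
#' @param slide_id slide identifier.
#' @return an object of class `tissue_map`.
#' @export
tissue_map <- function(labels, mpp, slide_id = "slide") {
  if (!is.matrix(labels)) stil_stop("labels must be a matrix", "invalid_config")
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% TISSUE_CODES)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stil_stop(sprintf("illegal tissue label code %d at pixel %d",
                      labels[idx], idx), "parse_error")
  }
  if (!is.numeric(mpp) || length(mpp) != 1L || mpp <= 0) {
    stil_stop("mpp must be a positive scalar", "invalid_config")
  }
  structure(list(labels = labels, mpp = as.numeric(mpp),
                 slide_id = as.character(slide_id)),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  dims <- dim(x$labels)
  cat(sprintf("tissue_map '%s': %d x %d px @ %.3g um/px (%.3g x %.3g um)\n",
              x$slide_id, dims[1], dims[2], x$mpp,
              dims[2] * x$mpp, dims[1] * x$mpp))
  fr <- table(factor(x$labels, levels = TISSUE_CODES)) / length(x$labels)
  cat(sprintf("  background %.1f%% | cancer %.1f%% | stroma %.1f%%\n",
              100 * fr[1], 100 * fr[2], 100 * fr[3]))
  invisible(x)
}

#' Stroma area of a tissue map in square microns
#'
#' Defined as the stroma pixel count times mpp^2, exactly the denominator
#' used by the sTIL score.
#'
#' @param map a `tissue_map`.
#' @return area in um^2.
#' @export
stroma_area <- function(map) {
  sum(map$labels == TISSUE_CODES[["stroma"]]) * map$mpp^2
}

#' Cancer area of a tissue map in square microns
#' @param map a `tissue_map`.
#' @return area in um^2.
#' @export
cancer_area <- function(map) {
  sum(map$labels == TISSUE_CODES[["cancer"]]) * map$mpp^2
}

# Slide extent in microns, c(width, height).
slide_extent <- function(map) {
  c(width = ncol(map$labels) * map$mpp, height = nrow(map$labels) * map$mpp)
}

#' Generate a synthetic tissue map
#'
#' Thresholds a smooth Gaussian random field so that the highest-valued
#' pixels become cancer area and the adjacent band becomes cancer stroma,
#' yielding contiguous cancer nests ringed by stroma. Realized label
#' fractions equal the requested fractions up to one pixel (exact pixel
#' counts are allocated by rank), so the documented tolerance of +/- 0.05 on
#' realized fractions is met by construction.
#'
#' @param width_um,height_um slide extent in microns (> 0).
#' @param mpp microns per pixel (default 2).
#' @param stroma_fraction,cancer_fraction requested label fractions
#'   (each >= 0, sum <= 1).
#' @param seed integer seed; fixed seed gives a bit-identical raster.
#' @param correlation_um correlation length of the underlying field.
#' @param slide_id slide identifier.
#' @return a `tissue_map`.
#' @export
generate_tissue_map <- function(width_um, height_um, mpp = 2,
                                stroma_fraction = 0.4, cancer_fraction = 0.3,
                                seed = NULL,
                                correlation_um = width_um / 8,
                                slide_id = "slide") {
  if (width_um <= 0 || height_um <= 0 || mpp <= 0) {
    stil_stop("slide dimensions and mpp must be positive", "invalid_config")
  }
  if (stroma_fraction < 0 || cancer_fraction < 0 ||
      stroma_fraction + cancer_fraction > 1 + 1e-12) {
    stil_stop("label fractions must be >= 0 and sum to <= 1",
              "invalid_config")
  }
  nr <- max(1L, as.integer(round(height_um / mpp)))
  nc <- max(1L, as.integer(round(width_um / mpp)))
  with_seed(seed, {
    g <- smooth_gaussian_field(nr, nc, correlation_um / mpp)
    n <- nr * nc
    k_cancer <- round(cancer_fraction * n)
    k_stroma <- round(stroma_fraction * n)
    ord <- order(g, decreasing = TRUE)
    labels <- integer(n)
    if (k_cancer > 0) labels[ord[seq_len(k_cancer)]] <- TISSUE_CODES[["cancer"]]
    if (k_stroma > 0) {
      labels[ord[k_cancer + seq_len(k_stroma)]] <- TISSUE_CODES[["stroma"]]
    }
    tissue_map(matrix(labels, nr, nc), mpp, slide_id)
  })
}
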