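# Cell point tables and the doubly stochastic lymphoid point process.

CELL_CLASSES <- c("lymphoid", "tumor")

# Radius (um) of the sphere used to convert a lymphoid point count into an
# occupied-area percentage; lymphocytes are morphologically regular in size.
LYMPHOCYTE_RADIUS_UM <- 3

#' Construct a cell table
#'
#' A cell table records detected or ground-truth cell centroids in slide
#' coordinates (microns, origin top-left, y downward) with a class label.
#'
#' @param slide_id slide identifier (recycled).
#' @param x_um,y_um coordinates in microns (non-negative).
#' @param cell_class "lymphoid" or "tumor".
#' @return a data.frame of class `cell_table` with columns
#'   slide_id, x_um, y_um, cell_class.
#' @export
cell_table <- function(slide_id = character(), x_um = numeric(),
                       y_um = numeric(), cell_class = character()) {
  if (length(x_um) != length(y_um) ||
      (length(cell_class) != length(x_um) && length(cell_class) != 0)) {
    stil_stop("coordinate and class vectors must have equal length",
              "invalid_config")
  }
  if (any(x_um < 0) || any(y_um < 0)) {
    stil_stop("cell coordinates must be non-negative", "invalid_config")
  }
  if (!all(cell_class %in% CELL_CLASSES)) {
    stil_stop("cell_class must be 'lymphoid' or 'tumor'", "parse_error")
  }
  out <- data.frame(slide_id = as.character(rep_len(slide_id,
                                                    length(x_um))),
                    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                    cell_class = as.character(cell_class),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Intensity configuration for the lymphoid point process
#'
#' @param base_density expected lymphoid cells per mm^2 of cancer stroma.
#' @param heterogeneity dispersion of the random log-intensity field
#'   (0 = homogeneous Poisson; larger values give stronger spatial
#'   clustering at fixed expected count).
#' @param field_correlation_length correlation length of the intensity
#'   field in microns.
#' @param tumor_density expected tumor cells per mm^2 of cancer area.
#' @param cancer_lymphoid_fraction fraction of `base_density` also applied
#'   inside cancer area (default 0: lymphoid cells confined to stroma).
#' @return an `intensity_config` list.
#' @export
intensity_config <- function(base_density = 8000, heterogeneity = 1,
                             field_correlation_length = 200,
                             tumor_density = 2000,
                             cancer_lymphoid_fraction = 0) {
  if (base_density < 0 || tumor_density < 0 || heterogeneity < 0 ||
      cancer_lymphoid_fraction < 0) {
    stil_stop("densities and heterogeneity must be >= 0", "invalid_config")
  }
  structure(list(base_density = base_density, heterogeneity = heterogeneity,
                 field_correlation_length = field_correlation_length,
                 tumor_density = tumor_density,
                 cancer_lymphoid_fraction = cancer_lymphoid_fraction),
            class = "intensity_config")
}

# Sample per-pixel Poisson counts with rates lambda (one per pixel index
# idx into the raster), returning jittered micron coordinates.
sample_pixel_points <- function(idx, lambda, nr, mpp) {
  counts <- stats::rpois(length(idx), lambda)
  pos <- rep(idx, counts)
  n <- length(pos)
  if (n == 0L) return(data.frame(x_um = numeric(), y_um = numeric()))
  row <- ((pos - 1L) %% nr) + 1L
  col <- ((pos - 1L) %/% nr) + 1L
  data.frame(x_um = (col - 1 + stats::runif(n)) * mpp,
             y_um = (row - 1 + stats::runif(n)) * mpp)
}

#' Generate cell detections on a tissue map
#'
#' Lymphoid cells follow a doubly stochastic (log-Gaussian Cox style)
#' process: a smooth Gaussian field with the configured correlation length
#' is exponentiated with gain `heterogeneity` and normalized to preserve the
#' mean density over stroma; per-pixel counts are then Poisson with the
#' resulting piecewise-constant intensity, which is exactly an inhomogeneous
#' Poisson process thinned against the same field. Tumor cells follow a
#' homogeneous Poisson process on cancer-area pixels. With
#' `heterogeneity = 0` the lymphoid pattern is homogeneous Poisson with
#' total mean `base_density * stroma area`.
#'
#' @param map a `tissue_map`.
#' @param cfg an `intensity_config`.
#' @param seed integer seed.
#' @return a `cell_table`; lymphoid rows lie on stroma pixels (plus cancer
#'   pixels when `cancer_lymphoid_fraction > 0`), tumor rows on cancer
#'   pixels.
#' @export
generate_cells <- function(map, cfg = intensity_config(), seed = NULL) {
  stopifnot(inherits(map, "tissue_map"), inherits(cfg, "intensity_config"))
  nr <- nrow(map$labels)
  px_mm2 <- map$mpp^2 / 1e6  # pixel area in mm^2
  with_seed(seed, {
    stroma_idx <- which(map$labels == TISSUE_CODES[["stroma"]])
    cancer_idx <- which(map$labels == TISSUE_CODES[["cancer"]])
    if (cfg$heterogeneity > 0) {
      g <- smooth_gaussian_field(nr, ncol(map$labels),
                                 cfg$field_correlation_length / map$mpp)
      field <- exp(cfg$heterogeneity * g)
    } else {
      field <- NULL
    }
    lym <- data.frame(x_um = numeric(), y_um = numeric())
    if (length(stroma_idx) > 0 && cfg$base_density > 0) {
      f <- if (is.null(field)) 1 else {
        fs <- field[stroma_idx]
        fs / mean(fs)  # preserve the configured mean density
      }
      lym <- sample_pixel_points(stroma_idx,
                                 cfg$base_density * px_mm2 * f, nr, map$mpp)
    }
    if (length(cancer_idx) > 0 && cfg$cancer_lymphoid_fraction > 0 &&
        cfg$base_density > 0) {
      f <- if (is.null(field)) 1 else {
        fc <- field[cancer_idx]
        fc / mean(fc)
      }
      extra <- sample_pixel_points(
        cancer_idx,
        cfg$cancer_lymphoid_fraction * cfg$base_density * px_mm2 * f,
        nr, map$mpp)
      lym <- rbind(lym, extra)
    }
    tum <- data.frame(x_um = numeric(), y_um = numeric())
    if (length(cancer_idx) > 0 && cfg$tumor_density > 0) {
      tum <- sample_pixel_points(cancer_idx,
                                 rep(cfg$tumor_density * px_mm2,
                                     length(cancer_idx)), nr, map$mpp)
    }
    cell_table(map$slide_id,
               c(lym$x_um, tum$x_um), c(lym$y_um, tum$y_um),
               c(rep("lymphoid", nrow(lym)), rep("tumor", nrow(tum))))
  })
}

# Linear raster indices of cell positions.
cell_pixel_index <- function(cells, map) {
  nr <- nrow(map$labels)
  nc <- ncol(map$labels)
  row <- um_to_px(cells$y_um, map$mpp, nr)
  col <- um_to_px(cells$x_um, map$mpp, nc)
  (col - 1L) * nr + row
}

# Count lymphoid cells whose pixel carries the stroma label.
count_lymphoid_in_stroma <- function(cells, map) {
  lym <- cells[cells$cell_class == "lymphoid", , drop = FALSE]
  if (nrow(lym) == 0L) return(0L)
  idx <- cell_pixel_index(lym, map)
  sum(map$labels[idx] == TISSUE_CODES[["stroma"]])
}

#' Geometric ground-truth sTIL of a synthetic slide
#'
#' The true stromal TIL percentage is the fraction of stroma area occupied
#' by lymphoid cells, each modeled as a disc of radius 3 um:
#' `100 * pi * 3^2 * count / stroma_area`, clamped to \[0, 100\]. Tumor-cell
#' rows do not enter the computation.
#'
#' @param map a `tissue_map`.
#' @param cells a `cell_table` for the same slide.
#' @return a `slide_truth` list with fields slide_id, true_stil,
#'   stroma_area_um2, lymphoid_in_stroma.
#' @export
true_stil <- function(map, cells) {
  area <- stroma_area(map)
  if (area <= 0) {
    stil_stop("sTIL undefined: slide has no cancer stroma", "undefined_score")
  }
  n <- count_lymphoid_in_stroma(cells, map)
  val <- 100 * pi * LYMPHOCYTE_RADIUS_UM^2 * n / area
  structure(list(slide_id = map$slide_id,
                 true_stil = min(max(val, 0), 100),
                 stroma_area_um2 = area,
                 lymphoid_in_stroma = n),
            class = "slide_truth")
}
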