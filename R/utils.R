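# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that every seeded operation
#' is a pure function of (inputs, seed) without clobbering the global stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Draw n sub-seeds (< 2^31) from a master seed, for per-slide reproducibility.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Classed error so callers/tests can distinguish failure modes.
stil_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "stilflow_error")))
}

# Stationary Gaussian random field: white noise on a coarse lattice, blurred
# with a separable Gaussian kernel (circular edges), standardized, then
# bilinearly upsampled to the target raster. sigma_px is the correlation
# length in pixels of the target raster.
smooth_gaussian_field <- function(nr, nc, sigma_px) {
  if (sigma_px <= 0) {
    return(matrix(stats::rnorm(nr * nc), nr, nc))
  }
  step <- max(1L, as.integer(floor(sigma_px / 2)))
  sig <- sigma_px / step
  half <- max(1L, as.integer(ceiling(3 * sig)))
  # coarse lattice must accommodate the kernel even for tiny rasters
  cr <- max(as.integer(ceiling(nr / step)) + 4L, 2L * half + 1L)
  cc <- max(as.integer(ceiling(nc / step)) + 4L, 2L * half + 1L)
  z <- matrix(stats::rnorm(cr * cc), cr, cc)
  k <- stats::dnorm(seq(-half, half), sd = sig)
  k <- k / sum(k)
  z <- conv_cols(z, k)
  z <- t(conv_cols(t(z), k))
  z <- (z - mean(z)) / stats::sd(z)
  if (step == 1L && cr >= nr && cc >= nc) {
    return(z[seq_len(nr), seq_len(nc), drop = FALSE])
  }
  bilinear_upsample(z, nr, nc, step)
}

# Column-wise 1-D convolution with circular boundary handling.
conv_cols <- function(z, k) {
  out <- stats::filter(z, k, method = "convolution", sides = 2,
                       circular = TRUE)
  matrix(as.numeric(out), nrow(z), ncol(z))
}

bilinear_upsample <- function(z, nr, nc, step) {
  ri <- (seq_len(nr) - 0.5) / step + 1
  ci <- (seq_len(nc) - 0.5) / step + 1
  r0 <- pmin(pmax(floor(ri), 1), nrow(z) - 1)
  c0 <- pmin(pmax(floor(ci), 1), ncol(z) - 1)
  fr <- pmin(pmax(ri - r0, 0), 1)
  fc <- pmin(pmax(ci - c0, 0), 1)
  z[r0, c0] * ((1 - fr) %o% (1 - fc)) +
    z[r0 + 1L, c0] * (fr %o% (1 - fc)) +
    z[r0, c0 + 1L] * ((1 - fr) %o% fc) +
    z[r0 + 1L, c0 + 1L] * (fr %o% fc)
}

# Summed-area table padded with a leading zero row/column, enabling O(1)
# rectangle sums: sat_sum(sat, r1, r2, c1, c2) over inclusive pixel ranges.
summed_area_table <- function(m) {
  ii <- apply(m, 2, cumsum)
  if (is.null(dim(ii))) ii <- matrix(ii, nrow(m), ncol(m))
  ii <- t(apply(ii, 1, cumsum))
  rbind(0, cbind(0, ii))
}

sat_sum <- function(sat, r1, r2, c1, c2) {
  sat[cbind(r2 + 1L, c2 + 1L)] - sat[cbind(r1, c2 + 1L)] -
    sat[cbind(r2 + 1L, c1)] + sat[cbind(r1, c1)]
}

# Convert micron coordinates to 1-based raster indices (floor convention,
# origin top-left, y downward).
um_to_px <- function(coord, mpp, n) {
  pmin(pmax(as.integer(floor(coord / mpp)) + 1L, 1L), n)
}
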