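# Small fixtures built in code.

# Map with a hand-laid geometry: left columns stroma, middle cancer,
# right background.
banded_map <- function(nr = 40, nc = 60, mpp = 2, slide_id = "fix") {
  labels <- matrix(0L, nr, nc)
  labels[, 1:(nc %/% 3)] <- 2L
  labels[, (nc %/% 3 + 1):(2 * nc %/% 3)] <- 1L
  tissue_map(labels, mpp, slide_id)
}

# All-stroma map whose stroma area is exactly `area_mm2` square millimetres.
stroma_block_map <- function(area_mm2 = 1, mpp = 4, slide_id = "blk") {
  n_px <- round(area_mm2 * 1e6 / mpp^2)
  nr <- as.integer(floor(sqrt(n_px)))
  nc <- as.integer(n_px / nr)
  stopifnot(nr * nc * mpp^2 == area_mm2 * 1e6)
  tissue_map(matrix(2L, nr, nc), mpp, slide_id)
}

# Cells placed deterministically on given pixel centres.
cells_at <- function(map, rows, cols, class = "lymphoid") {
  cell_table(map$slide_id, (cols - 0.5) * map$mpp, (rows - 0.5) * map$mpp,
             rep(class, length(rows)))
}

# Panel from a plain matrix with an optional automated column "DL".
panel_of <- function(m, automated = FALSE) {
  roles <- rep("human", ncol(m))
  if (automated) roles[ncol(m)] <- "automated"
  score_panel(m, roles)
}

# A noiseless, unbiased rater whose single field covers any desk-scale
# slide, reporting at integer grain.
exact_rater <- function(id = "X", ...) {
  rater_profile(id, k_fields = 1, field_size = 1e6, additive_bias = 0,
                multiplicative_bias = 1, noise_sd = 0, rounding_grain = 1,
                ...)
}
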