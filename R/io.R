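# Plain-text readers/writers: cell tables and panels as CSV, tissue maps as
# PGM (P2) with metadata in a comment line.

#' Write / read a cell table as CSV
#'
#' Header `slide_id,x_um,y_um,cell_class`. Round-trips exactly for the
#' printed precision (coordinates are written with full precision).
#'
#' @param cells a `cell_table`.
#' @param path file path.
#' @return `read_cell_table` returns a `cell_table`.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells)[, c("slide_id", "x_um", "y_um",
                                            "cell_class")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "x_um", "y_um", "cell_class")
  if (!all(need %in% names(df))) {
    stil_stop(sprintf("cell table %s: expected header %s", path,
                      paste(need, collapse = ",")), "parse_error")
  }
  bad <- which(!df$cell_class %in% CELL_CLASSES)
  if (length(bad)) {
    stil_stop(sprintf("cell table %s: illegal cell_class '%s' at row %d",
                      path, df$cell_class[bad[1]], bad[1]), "parse_error")
  }
  cell_table(df$slide_id, df$x_um, df$y_um, df$cell_class)
}

#' Write / read a tissue map as plain PGM (P2)
#'
#' The raster is stored as a portable graymap with maxval 2; the scale and
#' slide id travel in a comment line `# mpp=<value> slide_id=<id>` directly
#' after the magic number. Codes outside {0, 1, 2} are a parse error.
#'
#' @param map a `tissue_map`.
#' @param path file path.
#' @return `read_tissue_map` returns a `tissue_map`.
#' @export
write_tissue_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# mpp=%.10g slide_id=%s", map$mpp, map$slide_id),
               sprintf("%d %d", ncol(map$labels), nrow(map$labels)),
               "2"), con)
  writeLines(apply(map$labels, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_tissue_map
#' @export
read_tissue_map <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || trimws(lines[1]) != "P2") {
    stil_stop(sprintf("%s: not a plain (P2) PGM file", path), "parse_error")
  }
  mpp <- 1
  slide_id <- "slide"
  comments <- grep("^#", lines)
  for (i in comments) {
    m <- regmatches(lines[i], regexec("mpp=([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2) mpp <- as.numeric(m[2])
    m <- regmatches(lines[i], regexec("slide_id=(\\S+)", lines[i]))[[1]]
    if (length(m) == 2) slide_id <- m[2]
  }
  body <- lines[-c(1, comments)]
  nums <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  nc <- nums[1]; nr <- nums[2]; maxval <- nums[3]
  vals <- nums[-(1:3)]
  if (length(vals) != nr * nc) {
    stil_stop(sprintf("%s: expected %d pixels, found %d", path, nr * nc,
                      length(vals)), "parse_error")
  }
  bad <- which(!vals %in% 0:2)
  if (length(bad)) {
    stil_stop(sprintf("%s: illegal tissue label code %g at pixel %d", path,
                      vals[bad[1]], bad[1]), "parse_error")
  }
  tissue_map(matrix(as.integer(vals), nr, nc, byrow = TRUE), mpp, slide_id)
}

#' Write / read a score panel as wide CSV
#'
#' One row per slide, one column per reader; missing entries are written as
#' empty fields and read back as NA (never as 0). Reader roles are stored
#' in a `#roles:` comment line.
#'
#' @param panel a `score_panel`.
#' @param path file path.
#' @return `read_score_panel` returns a `score_panel`.
#' @export
write_score_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#roles: %s",
                     paste(panel$roles, collapse = ",")), con)
  df <- data.frame(slide_id = rownames(panel$scores), panel$scores,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_score_panel
#' @export
read_score_panel <- function(path) {
  lines <- readLines(path)
  roles <- NULL
  if (grepl("^#roles:", lines[1])) {
    roles <- trimws(strsplit(sub("^#roles:", "", lines[1]), ",")[[1]])
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "slide_id") {
    stil_stop(sprintf("%s: first column must be slide_id", path),
              "parse_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$slide_id
  score_panel(m, roles)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `stil_cohort` data.frame.
#' @param path file path.
#' @return `read_cohort` returns a `stil_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "subtype", "mp_grade", "responder")
  if (!all(need %in% names(df))) {
    stil_stop(sprintf("cohort %s: missing columns %s", path,
                      paste(setdiff(need, names(df)), collapse = ",")),
              "parse_error")
  }
  if (any(!df$mp_grade %in% 1:5)) {
    stil_stop(sprintf("cohort %s: Miller-Payne grade out of range", path),
              "invalid_record")
  }
  df$subtype <- factor(df$subtype, levels = c("HER2_positive", "TNBC"))
  df$responder <- as.logical(df$responder)
  class(df) <- c("stil_cohort", "data.frame")
  df
}
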