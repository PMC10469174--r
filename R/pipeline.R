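# End-to-end orchestration of the synthetic reader study: generate slides,
# score, triage, revise, and analyze response.

# lymphoid density (per mm^2 of stroma) that yields a given geometric sTIL
stil_to_density <- function(stil_pct) {
  stil_pct / 100 * 1e6 / (pi * LYMPHOCYTE_RADIUS_UM^2)
}

#' Default configuration for a full synthetic reader study
#'
#' A desk-scale study: about two hundred 1.02 x 1.02 mm slides at 2 um/px,
#' per-slide true sTIL drawn from a Beta model with cohort mean 22.7% and
#' SD 19.3%, four simulated raters (two scoring all slides, two splitting
#' the remainder so that every slide carries three human scores), and one
#' automated reader with imperfect recall and stroma segmentation.
#'
#' @param n_slides number of slides (default 203, matching the default
#'   cohort size).
#' @param seed master seed.
#' @return a nested configuration list.
#' @export
default_study_config <- function(n_slides = 203, seed = 1) {
  list(
    n_slides = n_slides,
    slide = list(width_um = 1024, height_um = 1024, mpp = 2,
                 stroma_fraction = 0.4, cancer_fraction = 0.35,
                 correlation_um = 180),
    stil = list(mean = 22.7, sd = 19.3, min = 0.5, max = 90),
    intensity = list(heterogeneity = 1.2, field_correlation_length = 200,
                     tumor_density = 2000),
    raters = default_rater_profiles(),
    reader = reader_error_profile(),
    scoring = scoring_config(),
    triage = triage_config(),
    strata = stratum_config(),
    cohort = cohort_config(),
    revision_noise_sd = 0,
    detection_metric_slides = 20,
    seed = seed)
}

# Assignment of human raters to slides: the first two raters score every
# slide, the remaining raters split the cohort so each slide has three
# human scores (mirroring a two-full/two-partial reader design).
default_rater_design <- function(n_slides, rater_ids) {
  k <- length(rater_ids)
  design <- matrix(FALSE, n_slides, k,
                   dimnames = list(NULL, rater_ids))
  design[, seq_len(min(2, k))] <- TRUE
  if (k >= 3) {
    split_at <- round(0.637 * n_slides)  # partial readers' share
    design[seq_len(split_at), 3] <- TRUE
    if (k >= 4) {
      design[setdiff(seq_len(n_slides), seq_len(split_at)), 4] <- TRUE
    }
  }
  design
}

#' Run the full synthetic reader study
#'
#' Pipeline: generate tissue maps and cell patterns; score each slide with
#' the simulated raters and the automated reader; compute initial pairwise
#' concordance and per-case COV; evaluate the automated reader standalone
#' on the initially concordant subset; triage against the automated score;
#' simulate the assisted revision; recompute concordance; account for
#' revisits/rescores; and run the response analysis per reading mode and
#' subtype subset on a cohort built from the same slides.
#'
#' @param config a configuration list as from [default_study_config()].
#' @param seed overrides `config$seed` when given.
#' @return a `stil_study` list with all intermediate and final results.
#' @export
run_full_study <- function(config = default_study_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  n <- config$n_slides
  seeds <- sub_seeds(config$seed, 3L * n + 10L)
  rater_ids <- names(config$raters)
  design <- default_rater_design(n, rater_ids)
  truths <- sample_slide_truths(n, config$stil$mean, config$stil$sd,
                                seed = seeds[1L])
  truths$true_stil <- pmin(pmax(truths$true_stil, config$stil$min),
                           config$stil$max)
  scores <- matrix(NA_real_, n, length(rater_ids) + 1L,
                   dimnames = list(truths$slide_id,
                                   c(rater_ids, "DL")))
  realized_iou <- numeric(n)
  realized_stil <- numeric(n)
  det_f1 <- NULL
  n_metric <- min(config$detection_metric_slides, n)
  for (i in seq_len(n)) {
    map <- generate_tissue_map(
      config$slide$width_um, config$slide$height_um, config$slide$mpp,
      config$slide$stroma_fraction, config$slide$cancer_fraction,
      seed = seeds[3L * (i - 1L) + 2L],
      correlation_um = config$slide$correlation_um,
      slide_id = truths$slide_id[i])
    icfg <- intensity_config(
      base_density = stil_to_density(truths$true_stil[i]),
      heterogeneity = config$intensity$heterogeneity,
      field_correlation_length = config$intensity$field_correlation_length,
      tumor_density = config$intensity$tumor_density)
    cells <- generate_cells(map, icfg, seed = seeds[3L * (i - 1L) + 3L])
    realized_stil[i] <- true_stil(map, cells)$true_stil
    si <- seeds[3L * (i - 1L) + 4L]
    for (j in seq_along(rater_ids)) {
      if (!design[i, j]) next
      scores[i, j] <- simulate_rater(map, cells, config$raters[[j]],
                                     seed = si + j)
    }
    dl <- simulate_dl_reader(map, cells, config$reader, config$scoring,
                             seed = si + length(rater_ids) + 1L)
    scores[i, "DL"] <- dl$score
    realized_iou[i] <- dl$realized_iou
    if (i <= n_metric) {
      met <- detection_metrics(cells, dl$cells, truth_map = map,
                               degraded_map = dl$map)
      f1 <- met$f1
      f1$slide_id <- truths$slide_id[i]
      f1$stroma_iou <- met$iou[["stroma"]]
      det_f1 <- rbind(det_f1, f1)
    }
  }
  roles <- c(rep("human", length(rater_ids)), "automated")
  panel <- score_panel(scores, roles)
  initial_ccc <- pairwise_ccc(panel, rater_ids)
  initial_cov <- cov_per_case(panel)
  triage <- triage_panel(panel, cfg = config$triage)
  concordant <- triage$concordance$slide_id[!triage$concordance$discordant]
  standalone <- NULL
  if (length(concordant) >= 3) {
    hm <- rowMeans(human_scores(panel)[concordant, , drop = FALSE],
                   na.rm = TRUE)
    standalone <- lins_ccc(hm, panel$scores[concordant, "DL"])
  }
  outcome <- simulate_revision(panel, config$raters, triage,
                               seed = seeds[3L * n + 5L],
                               noise_sd = config$revision_noise_sd)
  revised_ccc <- pairwise_ccc(outcome$panel, rater_ids)
  revised_cov <- cov_per_case(outcome$panel)
  accounting <- revision_accounting(triage, outcome, panel,
                                    cfg = config$triage)
  slides <- truths
  slides$stil_initial <- rowMeans(human_scores(panel), na.rm = TRUE)
  slides$stil_revised <- rowMeans(human_scores(outcome$panel),
                                  na.rm = TRUE)
  slides$stil_automated <- scores[, "DL"]
  cohort_cfg <- config$cohort
  if (cohort_cfg$n_total > n) {
    stil_stop("cohort n_total exceeds n_slides", "invalid_config")
  }
  cohort <- generate_cohort(cohort_cfg, slides, seed = seeds[3L * n + 6L])
  response <- list()
  for (mode in c("initial", "revised", "automated")) {
    for (ss in c("all", "HER2_positive", "TNBC")) {
      response[[paste(mode, ss, sep = ".")]] <-
        tryCatch(response_analysis(cohort, mode, ss, config$strata),
                 stilflow_error = function(e) NULL)
    }
  }
  structure(list(config = config, slides = slides, panel = panel,
                 initial_ccc = initial_ccc, initial_cov = initial_cov,
                 standalone_ccc = standalone, triage = triage,
                 outcome = outcome, revised_ccc = revised_ccc,
                 revised_cov = revised_cov, accounting = accounting,
                 realized_iou = realized_iou,
                 realized_stil = realized_stil,
                 detection_f1 = det_f1, cohort = cohort,
                 response = response),
            class = "stil_study")
}

#' @export
print.stil_study <- function(x, ...) {
  cat(sprintf("synthetic sTIL reader study: %d slides, %d raters + DL\n",
              x$config$n_slides, length(x$config$raters)))
  cat(sprintf("  initial discordant: %d (%.1f%%)\n",
              x$accounting$before_discordant,
              100 * x$accounting$discordant_fraction_before))
  cat(sprintf("  after revision:     %d (%.1f%%), McNemar p = %.3g\n",
              x$accounting$after_discordant,
              100 * x$accounting$discordant_fraction_after,
              x$accounting$mcnemar$p_value))
  cat(sprintf("  COV %.3f +/- %.3f -> %.3f +/- %.3f\n",
              x$initial_cov$mean, x$initial_cov$sd,
              x$revised_cov$mean, x$revised_cov$sd))
  if (!is.null(x$standalone_ccc)) {
    cat(sprintf("  standalone CCC on concordant subset: %.3f\n",
                x$standalone_ccc$estimate))
  }
  invisible(x)
}

#' Write the study's machine-readable report bundle
#'
#' JSON with all agreement and accounting statistics plus CSV exports of
#' the score panels and cohort; every number is reproducible from
#' (config, seed).
#'
#' @param study a `stil_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- study$accounting
  report <- list(
    seed = study$config$seed,
    n_slides = study$config$n_slides,
    initial_ccc = study$initial_ccc$estimate,
    revised_ccc = study$revised_ccc$estimate,
    initial_cov = c(mean = study$initial_cov$mean,
                    sd = study$initial_cov$sd),
    revised_cov = c(mean = study$revised_cov$mean,
                    sd = study$revised_cov$sd),
    standalone_ccc = if (!is.null(study$standalone_ccc))
      unclass(study$standalone_ccc),
    accounting = unclass(acc),
    mean_realized_iou = mean(study$realized_iou),
    response = lapply(study$response, function(r) {
      if (is.null(r)) return(NULL)
      list(mode = r$mode, subset = r$subset, n = r$n,
           mean_responder = r$mean_responder,
           mean_nonresponder = r$mean_nonresponder,
           p_value = if (!is.null(r$t_test)) r$t_test$p_value,
           or_table = r$or_table)
    }))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_score_panel(study$panel, file.path(dir, "panel_initial.csv"))
  write_score_panel(study$outcome$panel,
                    file.path(dir, "panel_revised.csv"))
  write_cohort(study$cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' Read a study configuration from YAML
#'
#' Entries present in the file override the defaults; rater and reader
#' profiles are rebuilt through their constructors so invariants are
#' enforced.
#'
#' @param path YAML file path.
#' @return a configuration list as from [default_study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_study_config()
  for (key in intersect(names(raw), c("n_slides", "seed",
                                      "revision_noise_sd",
                                      "detection_metric_slides"))) {
    cfg[[key]] <- raw[[key]]
  }
  for (key in intersect(names(raw), c("slide", "stil", "intensity"))) {
    cfg[[key]][names(raw[[key]])] <- raw[[key]]
  }
  if (!is.null(raw$scoring)) cfg$scoring <- do.call(scoring_config,
                                                    raw$scoring)
  if (!is.null(raw$triage)) cfg$triage <- do.call(triage_config,
                                                  raw$triage)
  if (!is.null(raw$strata)) cfg$strata <- do.call(stratum_config,
                                                  raw$strata)
  if (!is.null(raw$cohort)) cfg$cohort <- do.call(cohort_config,
                                                  raw$cohort)
  if (!is.null(raw$reader)) cfg$reader <- do.call(reader_error_profile,
                                                  raw$reader)
  if (!is.null(raw$raters)) {
    cfg$raters <- lapply(names(raw$raters), function(id) {
      do.call(rater_profile, c(list(rater_id = id), raw$raters[[id]]))
    })
    names(cfg$raters) <- names(raw$raters)
  }
  cfg
}
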