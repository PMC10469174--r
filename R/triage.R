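# Concordant/discordant triage, revisit flags against the automated score,
# simulated assisted revision, and revisit/rescore accounting.

#' Triage configuration
#'
#' @param threshold difference in percentage points that triggers triage
#'   (> 0, default 10).
#' @param inclusive if TRUE (default) a difference equal to the threshold
#'   triggers (concordant means strictly less than the threshold).
#' @return a `triage_config` list.
#' @export
triage_config <- function(threshold = 10, inclusive = TRUE) {
  if (threshold <= 0) stil_stop("threshold must be > 0", "invalid_config")
  structure(list(threshold = threshold, inclusive = isTRUE(inclusive)),
            class = "triage_config")
}

trigger <- function(diff, cfg) {
  if (cfg$inclusive) diff >= cfg$threshold else diff > cfg$threshold
}

#' Classify slides as concordant or discordant
#'
#' A slide is discordant when the maximum pairwise absolute difference
#' among its human scores reaches the threshold. Slides with fewer than two
#' human scores are excluded with a warning.
#'
#' @param panel a `score_panel`.
#' @param cfg a `triage_config`.
#' @return data.frame: slide_id, n_readers, max_diff, discordant; with
#'   attribute `counts` = c(concordant, discordant).
#' @export
classify_concordance <- function(panel, cfg = triage_config()) {
  hs <- human_scores(panel)
  n_readers <- rowSums(is.finite(hs))
  if (any(n_readers < 2)) {
    warning(sprintf("%d slide(s) with < 2 human scores excluded",
                    sum(n_readers < 2)))
  }
  keep <- n_readers >= 2
  hs <- hs[keep, , drop = FALSE]
  max_diff <- apply(hs, 1, function(v) {
    v <- v[is.finite(v)]
    max(v) - min(v)
  })
  out <- data.frame(slide_id = rownames(hs), n_readers = n_readers[keep],
                    max_diff = max_diff,
                    discordant = trigger(max_diff, cfg), row.names = NULL)
  attr(out, "counts") <- c(concordant = sum(!out$discordant),
                           discordant = sum(out$discordant))
  out
}

#' Flag a (slide, rater) pair for revisit against the automated score
#'
#' @param rater_score,automated_score sTIL percentages (vectorized).
#' @param cfg a `triage_config`.
#' @return logical; NA automated scores give FALSE with a warning, NA rater
#'   scores give NA (the rater did not score that slide).
#' @export
flag_revisit <- function(rater_score, automated_score,
                         cfg = triage_config()) {
  if (any(is.na(automated_score) & !is.na(rater_score))) {
    warning("missing automated score: revisit not flagged")
  }
  out <- trigger(abs(rater_score - automated_score), cfg)
  out[is.na(automated_score)] <- FALSE
  out[is.na(rater_score)] <- NA
  out
}

#' Triage a full panel against automated scores
#'
#' @param panel a `score_panel`.
#' @param automated named vector of automated scores per slide (defaults to
#'   the panel's automated reader column).
#' @param cfg a `triage_config`.
#' @return a `triage_result` list: concordance (per-slide data.frame),
#'   revisit (slide x human-rater logical matrix; NA where the rater did
#'   not score), config, automated.
#' @export
triage_panel <- function(panel, automated = NULL, cfg = triage_config()) {
  if (is.null(automated)) {
    auto_cols <- which(panel$roles == "automated")
    if (length(auto_cols) != 1L) {
      stil_stop("panel must carry exactly one automated reader",
                "invalid_config")
    }
    automated <- panel$scores[, auto_cols]
  }
  hs <- human_scores(panel)
  revisit <- matrix(NA, nrow(hs), ncol(hs), dimnames = dimnames(hs))
  for (j in seq_len(ncol(hs))) {
    revisit[, j] <- flag_revisit(hs[, j], automated, cfg)
  }
  structure(list(concordance = classify_concordance(panel, cfg),
                 revisit = revisit, config = cfg, automated = automated),
            class = "triage_result")
}

#' Simulate the assisted revision of flagged scores
#'
#' For each flagged (slide, rater) entry the rater rescores with
#' probability `revision_prob`, replacing the score by
#' `round((1 - w) * old + w * automated + eps)` clamped to \[0, 100\],
#' where `w` is the rater's reliance weight and `eps` optional Gaussian
#' noise. Unflagged entries are never altered.
#'
#' @param panel initial `score_panel`.
#' @param profiles named list of `rater_profile`s keyed by human reader
#'   name.
#' @param triage a `triage_result` computed on the same panel.
#' @param seed integer seed.
#' @param noise_sd SD of the revision noise eps in points (default 0,
#'   deterministic pull).
#' @return a `revision_outcome` list: panel (revised `score_panel`),
#'   rescored (logical matrix of draws), changed (logical matrix,
#'   revised != initial).
#' @export
simulate_revision <- function(panel, profiles, triage, seed = NULL,
                              noise_sd = 0) {
  revisit <- triage$revisit
  automated <- triage$automated
  scores <- panel$scores
  humans <- colnames(revisit)
  rescored <- changed <- matrix(FALSE, nrow(revisit), ncol(revisit),
                                dimnames = dimnames(revisit))
  with_seed(seed, {
    for (j in seq_along(humans)) {
      pr <- profiles[[humans[j]]]
      if (is.null(pr)) {
        stil_stop(sprintf("no profile for rater '%s'", humans[j]),
                  "invalid_config")
      }
      flagged <- which(revisit[, j] %in% TRUE)
      if (length(flagged) == 0L) next
      act <- stats::runif(length(flagged)) < pr$revision_prob
      idx <- flagged[act]
      if (length(idx) == 0L) next
      eps <- if (noise_sd > 0) stats::rnorm(length(idx), 0, noise_sd) else 0
      old <- scores[idx, humans[j]]
      if (pr$reliance_weight == 0 && noise_sd == 0) {
        # no pull and no noise: the score is left bit-identical
        rescored[idx, j] <- TRUE
        next
      }
      new <- round((1 - pr$reliance_weight) * old +
                     pr$reliance_weight * automated[idx] + eps)
      new <- pmin(pmax(new, 0), 100)
      scores[idx, humans[j]] <- new
      rescored[idx, j] <- TRUE
      changed[idx, j] <- new != old
    }
  })
  structure(list(panel = score_panel(scores, panel$roles),
                 rescored = rescored, changed = changed),
            class = "revision_outcome")
}

#' Revisit/rescore accounting
#'
#' "Revisited" means returned to a rater because the triage rule flagged
#' the (slide, rater) pair; "rescored" means the rater actually changed the
#' score. Reports per-rater revisited counts and rates over each rater's
#' evaluated slides, the number of unique revisited slides with its
#' multiplicity strata (how many slides were revisited by exactly k
#' raters), per-rater change rates, and - when initial and revised panels
#' are supplied - before/after discordant counts with the McNemar test on
#' the paired status changes.
#'
#' @param triage a `triage_result`, or a plain logical slide x rater
#'   revisit matrix (NA where the rater did not score the slide).
#' @param outcome a `revision_outcome`, or a plain logical matrix of
#'   changed flags (optional).
#' @param panel initial `score_panel` (optional, for before/after
#'   discordance).
#' @param cfg a `triage_config` used for the before/after classification.
#' @return a `revision_accounting` list.
#' @export
revision_accounting <- function(triage, outcome = NULL, panel = NULL,
                                cfg = triage_config()) {
  revisit <- if (inherits(triage, "triage_result")) triage$revisit else
    triage
  changed <- if (inherits(outcome, "revision_outcome")) outcome$changed else
    outcome
  evaluated <- !is.na(revisit)
  flagged <- revisit %in% TRUE
  dim(flagged) <- dim(revisit)
  per_rater <- data.frame(
    rater = colnames(revisit),
    n_evaluated = as.integer(colSums(evaluated)),
    n_revisited = as.integer(colSums(flagged)),
    row.names = NULL)
  per_rater$revisit_rate <- ifelse(per_rater$n_evaluated > 0,
                                   per_rater$n_revisited /
                                     per_rater$n_evaluated, 0)
  if (!is.null(changed)) {
    per_rater$n_rescored <- as.integer(colSums(matrix(changed %in% TRUE,
                                                      nrow(changed))))
    per_rater$change_rate <- ifelse(per_rater$n_revisited > 0,
                                    per_rater$n_rescored /
                                      per_rater$n_revisited, 0)
  }
  k <- rowSums(flagged)
  n_slides <- nrow(revisit)
  strata <- as.data.frame(table(multiplicity = k[k > 0]),
                          stringsAsFactors = FALSE)
  if (nrow(strata)) {
    strata$multiplicity <- as.integer(as.character(strata$multiplicity))
    names(strata)[2] <- "n_slides"
  } else {
    strata <- data.frame(multiplicity = integer(), n_slides = integer())
  }
  unique_revisited <- sum(k > 0)
  out <- list(per_rater = per_rater, strata = strata,
              unique_revisited = unique_revisited,
              unique_fraction = if (n_slides > 0)
                unique_revisited / n_slides else 0,
              n_slides = n_slides)
  if (!is.null(panel) && inherits(outcome, "revision_outcome")) {
    before <- suppressWarnings(classify_concordance(panel, cfg))
    after <- suppressWarnings(classify_concordance(outcome$panel, cfg))
    stopifnot(identical(before$slide_id, after$slide_id))
    b <- sum(before$discordant & !after$discordant)  # resolved
    cc <- sum(!before$discordant & after$discordant) # newly discordant
    out$before_discordant <- sum(before$discordant)
    out$after_discordant <- sum(after$discordant)
    out$discordant_fraction_before <- mean(before$discordant)
    out$discordant_fraction_after <- mean(after$discordant)
    out$mcnemar <- c(list(b = b, c = cc), mcnemar_test(b, cc))
  }
  structure(out, class = "revision_accounting")
}

#' @export
print.revision_accounting <- function(x, ...) {
  cat(sprintf("revisited: %d unique slides (%.1f%% of %d)\n",
              x$unique_revisited, 100 * x$unique_fraction, x$n_slides))
  print(x$per_rater)
  if (!is.null(x$mcnemar)) {
    cat(sprintf("discordant before/after: %d -> %d (McNemar p = %.3g)\n",
                x$before_discordant, x$after_discordant,
                x$mcnemar$p_value))
  }
  invisible(x)
}
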