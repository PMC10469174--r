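# Synthetic neoadjuvant-chemotherapy response cohorts with a logistic
# sTIL -> response link and Miller-Payne grades.

#' Cohort configuration
#'
#' The response model is a latent-logistic formulation: for slide i,
#' `latent_i = beta0 + beta_stil * sTIL_i / 10 + beta_subtype * 1[TNBC] +
#' e_i` with standard-logistic noise e_i. The Miller-Payne grade is
#' `1 + #(cutpoints < latent_i)` and the responder flag is grade >= 4. The
#' third cutpoint is fixed at 0 so that `P(responder) = plogis(linear
#' predictor)` exactly - refitting a binary logistic regression on a
#' generated cohort recovers the configured coefficients.
#'
#' @param n_total cohort size.
#' @param n_her2,n_tnbc subtype counts (must sum to `n_total`; defaults
#'   148 and 55).
#' @param beta0 intercept on the log-odds scale.
#' @param beta_stil log-odds of response per 10 percentage points of true
#'   sTIL.
#' @param beta_subtype log-odds offset for TNBC.
#' @param grade_cutpoints strictly increasing length-4 thresholds on the
#'   latent scale separating Miller-Payne grades 1-5; the third must be 0
#'   for the responder dichotomization to coincide with the logistic model.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_total = 203, n_her2 = 148, n_tnbc = 55,
                          beta0 = -0.95, beta_stil = 0.3,
                          beta_subtype = 0.2,
                          grade_cutpoints = c(-2.2, -1, 0, 1.4)) {
  if (n_her2 + n_tnbc != n_total) {
    stil_stop("n_her2 + n_tnbc must equal n_total", "invalid_config")
  }
  if (length(grade_cutpoints) != 4L || any(diff(grade_cutpoints) <= 0)) {
    stil_stop("grade_cutpoints must be strictly increasing, length 4",
              "invalid_config")
  }
  structure(list(n_total = n_total, n_her2 = n_her2, n_tnbc = n_tnbc,
                 beta0 = beta0, beta_stil = beta_stil,
                 beta_subtype = beta_subtype,
                 grade_cutpoints = grade_cutpoints),
            class = "cohort_config")
}

#' Sample slide-level true sTIL values
#'
#' Draws true sTIL percentages from a Beta distribution rescaled to
#' \[0, 100\] with moments matched to the requested mean and SD - a
#' right-skewed distribution typical of breast-cancer cohorts.
#'
#' @param n number of slides.
#' @param mean_stil,sd_stil target mean and SD in percent (defaults 22.7
#'   and 19.3, a reader-study cohort scale).
#' @param seed integer seed.
#' @return data.frame: slide_id, true_stil.
#' @export
sample_slide_truths <- function(n, mean_stil = 22.7, sd_stil = 19.3,
                                seed = NULL) {
  m <- mean_stil / 100
  v <- (sd_stil / 100)^2
  ab <- m * (1 - m) / v - 1
  if (ab <= 0) stil_stop("sd too large for a Beta model", "invalid_config")
  with_seed(seed, {
    data.frame(slide_id = sprintf("slide_%04d", seq_len(n)),
               true_stil = 100 * stats::rbeta(n, m * ab, (1 - m) * ab))
  })
}

#' Generate a response cohort from a slide library
#'
#' Assigns molecular subtypes, draws latent response propensities from the
#' configured logistic model on the true sTIL, maps them to Miller-Payne
#' grades via the cutpoints, and sets the responder flag to grade >= 4.
#' Score columns per reading mode (`stil_initial`, `stil_revised`,
#' `stil_automated`) are carried over from the slide library when present
#' and default to the true sTIL otherwise.
#'
#' @param cfg a `cohort_config`.
#' @param slides data.frame with at least slide_id and true_stil; at least
#'   `n_total` rows (the first `n_total` are used).
#' @param seed integer seed.
#' @return a `stil_cohort` data.frame.
#' @export
generate_cohort <- function(cfg = cohort_config(), slides = NULL,
                            seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(seed, {
    if (is.null(slides)) {
      slides <- sample_slide_truths(cfg$n_total)
    }
    if (nrow(slides) < cfg$n_total) {
      stil_stop("slide library smaller than n_total", "invalid_config")
    }
    slides <- slides[seq_len(cfg$n_total), , drop = FALSE]
    n <- cfg$n_total
    subtype <- rep("HER2_positive", n)
    subtype[sample.int(n, cfg$n_tnbc)] <- "TNBC"
    latent <- cfg$beta0 + cfg$beta_stil * slides$true_stil / 10 +
      cfg$beta_subtype * (subtype == "TNBC") + stats::rlogis(n)
    grade <- 1L + findInterval(latent, cfg$grade_cutpoints)
    get_mode <- function(col) {
      if (col %in% names(slides)) slides[[col]] else slides$true_stil
    }
    out <- data.frame(slide_id = slides$slide_id,
                      subtype = factor(subtype,
                                       levels = c("HER2_positive", "TNBC")),
                      mp_grade = grade,
                      responder = grade >= 4L,
                      stil_initial = get_mode("stil_initial"),
                      stil_revised = get_mode("stil_revised"),
                      stil_automated = get_mode("stil_automated"),
                      true_stil = slides$true_stil,
                      row.names = NULL)
    class(out) <- c("stil_cohort", "data.frame")
    out
  })
}
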