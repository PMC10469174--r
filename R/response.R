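# Miller-Payne dichotomization, sTIL strata, and binary logistic regression
# fit from first principles (IRLS with Wald inference).

#' Miller-Payne responder dichotomization
#'
#' Grades 4 and 5 (disappearance of more than 90% of tumor cells, or no
#' residual invasive carcinoma) are responders; grades 1-3 are
#' non-responders.
#'
#' @param grade integer vector with values in 1..5.
#' @return logical responder flag(s).
#' @export
mp_responder <- function(grade) {
  if (any(!grade %in% 1:5)) {
    stil_stop("Miller-Payne grade must be in 1..5", "invalid_record")
  }
  grade >= 4
}

#' Stratum configuration for sTIL grouping
#'
#' @param low_cut low/intermediate boundary (default 10: low means < 10).
#' @param high_cut intermediate/high boundary (default 50: high means
#'   >= 50).
#' @return a `stratum_config` list.
#' @export
stratum_config <- function(low_cut = 10, high_cut = 50) {
  if (!(low_cut > 0 && low_cut < high_cut && high_cut <= 100)) {
    stil_stop("need 0 < low_cut < high_cut <= 100", "invalid_config")
  }
  structure(list(low_cut = low_cut, high_cut = high_cut),
            class = "stratum_config")
}

#' Assign sTIL strata
#'
#' low if score < `low_cut`; intermediate if `low_cut` <= score <
#' `high_cut`; high if score >= `high_cut`.
#'
#' @param score sTIL percentage(s) in \[0, 100\].
#' @param cfg a `stratum_config`.
#' @return factor with levels low, intermediate, high.
#' @export
stil_stratum <- function(score, cfg = stratum_config()) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    stil_stop("scores must lie in [0, 100]", "invalid_config")
  }
  cut(score, breaks = c(-Inf, cfg$low_cut, cfg$high_cut, Inf),
      labels = c("low", "intermediate", "high"), right = FALSE)
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(X beta)` via IRLS; standard
#' errors come from the inverse observed information at the optimum, odds
#' ratios are `exp(beta)` with Wald 95% intervals `exp(beta +/- 1.96 SE)`.
#' The log-likelihood is tracked per iteration (non-decreasing).
#' Complete or quasi-complete separation (diverging coefficients) raises a
#' classed error with diagnostics rather than returning unstable estimates.
#'
#' @param x design matrix (an intercept column is prepended unless one is
#'   already present); must be full column rank.
#' @param y binary 0/1 (or logical) outcome.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @return a `logistic_fit` list: coefficients, se, vcov, or_table,
#'   loglik (per-iteration trace), iterations, converged.
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stil_stop("outcome must be binary 0/1", "invalid_config")
  }
  x <- as.matrix(x)
  has_intercept <- any(apply(x, 2, function(col) all(col == 1)))
  if (!has_intercept) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1)))
  }
  if (qr(x)$rank < ncol(x)) {
    stil_stop("design matrix is rank deficient", "invalid_config")
  }
  p <- ncol(x)
  beta <- numeric(p)
  ll <- numeric(0)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    ll <- c(ll, sum(y * eta - log1p(exp(eta))))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(x, x * w)
    beta_new <- drop(solve(H, crossprod(x, w * z)))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > 30) {
      stop(errorCondition(
        paste("separation detected: coefficients diverging;",
              sprintf("max |beta| = %.1f at iteration %d",
                      max(abs(beta)), it)),
        class = c("separation_error", "stilflow_error")))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  ll <- c(ll, sum(y * eta - log1p(exp(eta))))
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(x, x * w)
  vcov <- solve(H)
  se <- sqrt(diag(vcov))
  zq <- stats::qnorm(0.975)
  zval <- beta / se
  or_table <- data.frame(term = colnames(x), estimate = beta, se = se,
                         or = exp(beta),
                         ci_low = exp(beta - zq * se),
                         ci_high = exp(beta + zq * se),
                         p_value = 2 * stats::pnorm(-abs(zval)),
                         row.names = NULL)
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)), vcov = vcov,
                 or_table = or_table, loglik = ll, iterations = it,
                 converged = converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit (%d IRLS iterations, %s)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$or_table, digits = 4)
  invisible(x)
}

#' Response analysis for one reading mode and subset
#'
#' Computes (i) the responder vs non-responder mean sTIL comparison by
#' pooled-variance two-sample t test and (ii) a binary logistic regression
#' of the responder flag on sTIL stratum indicators (low as reference),
#' reporting odds ratios with Wald 95% intervals for high-vs-low and
#' intermediate-vs-low. Degenerate inputs (constant scores, empty strata,
#' separation) mark the affected result unavailable instead of failing.
#'
#' @param cohort a `stil_cohort` data.frame.
#' @param mode reading mode: "initial", "revised" or "automated".
#' @param subset "all", "HER2_positive" or "TNBC".
#' @param strata_cfg a `stratum_config`.
#' @return a `response_report` list.
#' @export
response_analysis <- function(cohort,
                              mode = c("initial", "revised", "automated"),
                              subset = c("all", "HER2_positive", "TNBC"),
                              strata_cfg = stratum_config()) {
  mode <- match.arg(mode)
  subset <- match.arg(subset)
  if (subset != "all") cohort <- cohort[cohort$subtype == subset, ,
                                        drop = FALSE]
  if (nrow(cohort) == 0L) stil_stop("empty subset", "invalid_config")
  score <- cohort[[paste0("stil_", mode)]]
  resp <- cohort$responder
  tt <- tryCatch(mean_tests(score[resp], score[!resp], paired = FALSE),
                 stilflow_error = function(e) NULL)
  stratum <- stil_stratum(score, strata_cfg)
  or_table <- data.frame(contrast = c("intermediate_vs_low",
                                      "high_vs_low"),
                         or = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p_value = NA_real_,
                         available = FALSE)
  fit <- NULL
  if (all(table(stratum) > 0)) {
    X <- cbind(intermediate = as.numeric(stratum == "intermediate"),
               high = as.numeric(stratum == "high"))
    fit <- tryCatch(fit_logistic(X, resp),
                    separation_error = function(e) NULL,
                    stilflow_error = function(e) NULL)
    if (!is.null(fit)) {
      rows <- match(c("intermediate", "high"), fit$or_table$term)
      or_table$or <- fit$or_table$or[rows]
      or_table$ci_low <- fit$or_table$ci_low[rows]
      or_table$ci_high <- fit$or_table$ci_high[rows]
      or_table$p_value <- fit$or_table$p_value[rows]
      or_table$available <- TRUE
    }
  }
  structure(list(mode = mode, subset = subset, n = nrow(cohort),
                 n_responder = sum(resp),
                 mean_responder = mean(score[resp]),
                 sd_responder = stats::sd(score[resp]),
                 mean_nonresponder = mean(score[!resp]),
                 sd_nonresponder = stats::sd(score[!resp]),
                 t_test = tt, or_table = or_table, fit = fit,
                 strata_n = table(stratum)),
            class = "response_report")
}

#' @export
print.response_report <- function(x, ...) {
  cat(sprintf("response analysis [%s scores, %s, n = %d]\n", x$mode,
              x$subset, x$n))
  cat(sprintf("  responder %.1f +/- %.1f vs non-responder %.1f +/- %.1f",
              x$mean_responder, x$sd_responder, x$mean_nonresponder,
              x$sd_nonresponder))
  if (!is.null(x$t_test)) cat(sprintf(" (p = %.3g)", x$t_test$p_value))
  cat("\n")
  print(x$or_table, digits = 3)
  invisible(x)
}
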