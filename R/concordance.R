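# Multi-reader agreement statistics: Lin's CCC, per-case COV, nonparametric
# Bland-Altman limits, exact/asymptotic McNemar, and mean comparisons.

#' Construct a score panel
#'
#' A score panel is a slide x reader matrix of sTIL percentages with missing
#' entries allowed (readers may score subsets). Each reader is tagged as
#' human or automated; concordance operations use human readers unless
#' stated otherwise.
#'
#' @param scores numeric matrix, rows = slides, cols = readers; values in
#'   \[0, 100\] or NA. Dimnames are used as slide and reader identifiers.
#' @param roles character vector (one per reader) of "human"/"automated";
#'   defaults to all human.
#' @return a `score_panel` list.
#' @export
score_panel <- function(scores, roles = NULL) {
  if (!is.matrix(scores)) stil_stop("scores must be a matrix",
                                    "invalid_config")
  if (any(scores < 0 | scores > 100, na.rm = TRUE)) {
    stil_stop("scores must lie in [0, 100]", "invalid_config")
  }
  if (is.null(rownames(scores))) {
    rownames(scores) <- sprintf("slide_%03d", seq_len(nrow(scores)))
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("reader_%d", seq_len(ncol(scores)))
  }
  if (is.null(roles)) roles <- rep("human", ncol(scores))
  if (length(roles) != ncol(scores) ||
      !all(roles %in% c("human", "automated"))) {
    stil_stop("roles must be 'human'/'automated', one per reader",
              "invalid_config")
  }
  names(roles) <- colnames(scores)
  structure(list(scores = scores, roles = roles), class = "score_panel")
}

# Human-reader submatrix of a panel.
human_scores <- function(panel) {
  panel$scores[, panel$roles == "human", drop = FALSE]
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements:
#' `rho_c = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with biased
#' (divide-by-n) moment estimators, as in Lin's original definition. The
#' 95% confidence interval uses the Fisher z-transform with Lin's asymptotic
#' variance.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped),
#'   n >= 3, not both constant.
#' @return an `agreement_stat` list: estimate, ci_low, ci_high, n.
#' @export
lins_ccc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stil_stop("need at least 3 paired observations",
                        "invalid_config")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    stil_stop("degenerate CCC: both vectors constant and equal",
              "degenerate_stat")
  }
  if (sx2 == 0 && sy2 == 0) {
    stil_stop("degenerate CCC: both vectors constant", "degenerate_stat")
  }
  rho <- 2 * sxy / denom
  ci <- ccc_confint(rho, sx2, sy2, sxy, mx, my, n)
  structure(list(estimate = rho, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "agreement_stat")
}

# Fisher-z CI with Lin's (1989) asymptotic variance. Degenerate geometry
# (perfect agreement or zero correlation) returns a collapsed/NA interval.
ccc_confint <- function(rho, sx2, sy2, sxy, mx, my, n, level = 0.95) {
  if (abs(rho) >= 1 - 1e-12) return(c(rho, rho))
  if (sx2 == 0 || sy2 == 0) return(c(NA_real_, NA_real_))
  r <- sxy / sqrt(sx2 * sy2)
  if (r == 0 || n < 3) return(c(NA_real_, NA_real_))
  u2 <- (mx - my)^2 / sqrt(sx2 * sy2)  # Lin's u^2
  v <- ((1 - r^2) * rho^2 / ((1 - rho^2) * r^2) +
          4 * rho^3 * (1 - rho) * u2 / (r * (1 - rho^2)^2) -
          2 * rho^4 * u2^2 / (r^2 * (1 - rho^2)^2)) / (n - 2)
  if (!is.finite(v) || v < 0) return(c(NA_real_, NA_real_))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(rho)
  sort(tanh(z + c(-1, 1) * zq * sqrt(v)))
}

#' @export
print.agreement_stat <- function(x, ...) {
  cat(sprintf("CCC %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$estimate, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Pairwise CCC matrix over a score panel
#'
#' Uses pairwise-complete slides; pairs sharing fewer than 3 slides are
#' marked unavailable (NA). The diagonal is 1.
#'
#' @param panel a `score_panel`.
#' @param readers optional subset of reader names (default: all readers).
#' @return list of matrices: estimate, ci_low, ci_high, n.
#' @export
pairwise_ccc <- function(panel, readers = colnames(panel$scores)) {
  m <- panel$scores[, readers, drop = FALSE]
  k <- ncol(m)
  est <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(readers, readers))
  nmat <- matrix(0L, k, k, dimnames = list(readers, readers))
  diag(est) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      cc <- tryCatch(lins_ccc(m[ok, i], m[ok, j]),
                     degenerate_stat = function(e) NULL)
      if (is.null(cc)) next
      est[i, j] <- est[j, i] <- cc$estimate
      lo[i, j] <- lo[j, i] <- cc$ci_low
      hi[i, j] <- hi[j, i] <- cc$ci_high
    }
  }
  list(estimate = est, ci_low = lo, ci_high = hi, n = nmat)
}

#' Per-slide coefficient of variation across human readers
#'
#' COV = sample SD (n-1 denominator) divided by the mean of each slide's
#' human scores; slides whose mean is 0 have COV 0 by convention. Slides
#' with fewer than 2 human scores are excluded with a warning.
#'
#' @param panel a `score_panel`.
#' @return list with `per_slide` (data.frame slide_id, n_readers, mean, sd,
#'   cov) and summary fields `mean` and `sd` over slides.
#' @export
cov_per_case <- function(panel) {
  hs <- human_scores(panel)
  n_readers <- rowSums(is.finite(hs))
  if (any(n_readers < 2)) {
    warning(sprintf("%d slide(s) with < 2 human scores excluded from COV",
                    sum(n_readers < 2)))
  }
  keep <- n_readers >= 2
  hs <- hs[keep, , drop = FALSE]
  m <- apply(hs, 1, mean, na.rm = TRUE)
  s <- apply(hs, 1, stats::sd, na.rm = TRUE)
  cv <- ifelse(m == 0, 0, s / m)
  per_slide <- data.frame(slide_id = rownames(hs),
                          n_readers = n_readers[keep],
                          mean = m, sd = s, cov = cv,
                          row.names = NULL)
  list(per_slide = per_slide, mean = mean(cv), sd = stats::sd(cv))
}

#' Nonparametric Bland-Altman limits of agreement
#'
#' Differences d = x - y are centered at their mean; the limits are the
#' empirical 2.5th and 97.5th percentiles computed by linear interpolation
#' between order statistics (the h = (n-1)p + 1 convention, i.e. R's
#' default quantile type 7).
#'
#' @param x,y paired vectors (pairs with missing values dropped), n >= 3.
#' @return a `ba_result` list: mean_diff, loa_low, loa_high, n.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  if (length(d) < 3L) stil_stop("need at least 3 pairs", "invalid_config")
  q <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(mean_diff = mean(d), loa_low = q[1], loa_high = q[2],
                 n = length(d)),
            class = "ba_result")
}

#' McNemar test for paired dichotomous status
#'
#' Takes the two off-diagonal discordant-pair counts. For b + c < 25 the
#' exact two-sided binomial p-value is used; otherwise the chi-squared
#' approximation with continuity correction `(|b - c| - 1)^2 / (b + c)`.
#' b = c = 0 gives p = 1.
#'
#' @param b,c non-negative integer counts of the two change directions.
#' @return list with statistic (NA for the exact branch), p_value, method.
#' @export
mcnemar_test <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stil_stop("b and c must be non-negative integers", "invalid_config")
  }
  n <- b + c
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = 1, method = "exact"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    return(list(statistic = NA_real_, p_value = p, method = "exact"))
  }
  stat <- (abs(b - c) - 1)^2 / n
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = "chi-squared with continuity correction")
}

#' Paired or two-sample t comparison of means
#'
#' Thin wrapper around [stats::t.test()] (pooled-variance Student's t for
#' the two-sample case) that raises a classed error when the relevant
#' variance is zero instead of returning a meaningless statistic.
#'
#' @param x,y numeric vectors (paired: equal length).
#' @param paired logical.
#' @return list with statistic, p_value, df, method, mean_x, mean_y.
#' @export
mean_tests <- function(x, y, paired = FALSE) {
  if (paired) {
    ok <- is.finite(x) & is.finite(y)
    d <- x[ok] - y[ok]
    if (length(d) < 2L || stats::sd(d) == 0) {
      stil_stop("degenerate paired t: zero-variance differences",
                "degenerate_stat")
    }
    ht <- stats::t.test(x[ok], y[ok], paired = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                df = unname(ht$parameter), method = ht$method,
                mean_x = mean(x[ok]), mean_y = mean(y[ok])))
  } else {
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      stil_stop("need n >= 2 per group", "invalid_config")
    }
    pooled <- ((length(x) - 1) * stats::var(x) +
                 (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    if (pooled == 0) {
      stil_stop("degenerate t test: zero pooled variance",
                "degenerate_stat")
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), method = ht$method,
       mean_x = mean(x), mean_y = mean(y))
}
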