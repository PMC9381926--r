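#' Bland-Altman agreement between measured and calculated PAWP
#'
#' @param truth Reference values (e.g. catheter PAWP), mmHg.
#' @param estimate Calculated values (e.g. from the inverted calibration),
#'   mmHg.
#' @return An `la_bland_altman` list: `bias` (mean of `truth - estimate`),
#'   `sd_diff` (sample SD of the differences), `loa_low`, `loa_high`
#'   (bias -/+ 1.96 sd), `n`.
#' @export
bland_altman <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("paired vectors must have equal length", call. = FALSE)
  ok <- is.finite(truth) & is.finite(estimate)
  d <- truth[ok] - estimate[ok]
  if (length(d) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "la_bland_altman")
}

# empirical (midrank) AUC: equivalent to (concordant + ties/2) / (n+ * n-)
.auc_midrank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (as.numeric(n_pos) * n_neg)
}

# sensitivity/specificity of the rule score > cutoff, with exact
# Clopper-Pearson 95% binomial confidence intervals
.sens_spec_at <- function(scores, positive, cutoff, conf_level = 0.95) {
  tp <- sum(scores[positive] > cutoff); np <- sum(positive)
  tn <- sum(scores[!positive] <= cutoff); nn <- sum(!positive)
  ci <- function(k, n) as.numeric(stats::binom.test(
    k, n, conf.level = conf_level)$conf.int)
  list(cutoff = cutoff,
       sensitivity = tp / np, sens_ci = ci(tp, np),
       specificity = tn / nn, spec_ci = ci(tn, nn))
}

#' ROC analysis of the acceleration factor
#'
#' Evaluates the classification rule `alpha > cutoff` for a binary state
#' (positivity defined by strict inequality, matching PAWP > 15 mmHg).
#' Thresholds are the midpoints between consecutive sorted unique scores
#' plus infinite sentinels. Reports the empirical (midrank) AUC with a
#' DeLong 95% confidence interval, the Youden cut-off (lowest threshold
#' maximizing sensitivity + specificity), and, when a calibration model is
#' supplied, the regression-derived cut-off `a + b * threshold_pawp`
#' together with exact Clopper-Pearson confidence intervals for
#' sensitivity and specificity at both cut-offs.
#'
#' @param scores Classifier values (acceleration factors).
#' @param positive Logical (or 0/1) disease state; both classes must occur.
#' @param calibration Optional `la_calibration` used for the
#'   regression-derived cut-off.
#' @param threshold_pawp PAWP threshold defining positivity, mmHg.
#' @param conf_level Confidence level for the interval estimates.
#' @return An `la_roc` list: `auc`, `ci95_auc`, `points` (threshold,
#'   sensitivity, specificity), `youden` and (optionally) `regression`
#'   cut-off summaries from the sensitivity/specificity rule above,
#'   `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, positive, calibration = NULL,
                         threshold_pawp = 15, conf_level = 0.95) {
  positive <- as.logical(positive)
  ok <- is.finite(scores) & !is.na(positive)
  scores <- scores[ok]; positive <- positive[ok]
  if (!any(positive) || all(positive))
    stop("both classes must be present for ROC analysis", call. = FALSE)

  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pts <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[positive] > t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[!positive] <= t),
                         numeric(1)))

  auc <- .auc_midrank(scores, positive)
  roc_obj <- pROC::roc(response = positive, predictor = scores,
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
  # pROC warns that the DeLong interval degenerates at AUC = 1; the value
  # it returns is still the correct degenerate interval
  ci_auc <- suppressWarnings(as.numeric(pROC::ci.auc(
    roc_obj, method = "delong", conf.level = conf_level)))[c(1, 3)]

  ysum <- pts$sensitivity + pts$specificity
  cut_y <- pts$threshold[which.max(ysum)]  # which.max -> lowest threshold
  youden <- .sens_spec_at(scores, positive, cut_y, conf_level)

  regression <- NULL
  if (!is.null(calibration)) {
    cut_r <- calibration$intercept_a + calibration$slope_b * threshold_pawp
    regression <- .sens_spec_at(scores, positive, cut_r, conf_level)
  }
  structure(list(auc = auc, ci95_auc = ci_auc, points = pts,
                 youden = youden, regression = regression,
                 n_pos = sum(positive), n_neg = sum(!positive)),
            class = "la_roc")
}
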