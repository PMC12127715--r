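#' Screening performance evaluation
#'
#' Discrimination and calibration statistics as used in screening validation
#' studies: detection rate (sensitivity) at a fixed false-positive rate with a
#' Wilson confidence interval, ROC AUC with a DeLong confidence interval,
#' calibration slope and intercept from logistic regression of outcomes on the
#' logit of predicted risk, and McNemar's paired test comparing two screening
#' methods thresholded at the same false-positive rate.
#'
#' @name evaluation
NULL

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels contain NA")
  if (!any(labels) || all(labels)) stop("evaluation requires both cases and controls")
  labels
}

#' Screen-positive threshold at a fixed false-positive rate
#'
#' The smallest observed control risk `t` such that the proportion of controls
#' with risk `>= t` is at most `fpr` (screening convention: flag the top of
#' the control distribution; ties are broken toward a lower realized FPR).
#'
#' @param risks numeric risks.
#' @param labels logical/0-1 outcome labels (TRUE = case).
#' @param fpr target false-positive rate.
#' @return the threshold.
#' @export
fpr_threshold <- function(risks, labels, fpr = 0.10) {
  labels <- check_two_classes(labels)
  if (any(!is.finite(risks))) stop("risks must be finite")
  ctrl <- sort(risks[!labels], decreasing = TRUE)
  n <- length(ctrl)
  k <- floor(fpr * n)            # max controls allowed at/above threshold
  if (k == 0) return(ctrl[1] * (1 + 1e-12) + 1e-300)
  t <- ctrl[k]
  # with ties, mean(ctrl >= t) can exceed fpr; step up until it does not
  while (mean(ctrl >= t) > fpr) {
    above <- ctrl[ctrl > t]
    if (!length(above)) return(ctrl[1] * (1 + 1e-12) + 1e-300)
    t <- min(above)
  }
  t
}

#' Detection rate at a fixed false-positive rate
#'
#' @inheritParams fpr_threshold
#' @param conf confidence level for the Wilson interval on the detection rate.
#' @return list with `dr`, `dr_ci`, `threshold`, `fpr_realized`, `n_cases`,
#'   `n_controls`.
#' @export
detection_rate_at_fpr <- function(risks, labels, fpr = 0.10, conf = 0.95) {
  labels <- check_two_classes(labels)
  t <- fpr_threshold(risks, labels, fpr)
  cases <- risks[labels]
  x <- sum(cases >= t)
  list(dr = x / length(cases),
       dr_ci = wilson_ci(x, length(cases), conf),
       threshold = t,
       fpr_realized = mean(risks[!labels] >= t),
       n_cases = length(cases),
       n_controls = sum(!labels))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney probability that a random case outranks a random
#' control, ties counted one half; the confidence interval is DeLong's
#' (via pROC).
#'
#' @inheritParams detection_rate_at_fpr
#' @return list with `auc` and `auc_ci`.
#' @export
roc_auc <- function(risks, labels, conf = 0.95) {
  labels <- check_two_classes(labels)
  if (any(!is.finite(risks))) stop("risks must be finite")
  r <- pROC::roc(response = labels, predictor = risks,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)), auc_ci = c(lower = ci[1], upper = ci[3]))
}

#' Calibration slope and intercept
#'
#' The calibration slope is the coefficient from logistic regression of the
#' observed outcome on the logit of the predicted risk; the calibration
#' intercept is calibration-in-the-large, i.e. the constant of the same
#' regression with the slope fixed at 1 (logit risk as an offset). Slope 1 and
#' intercept 0 mean the predicted risks equal observed incidences; the
#' intercept-given-slope-1 convention keeps the intercept interpretable as the
#' overall miscalibration of the risk level rather than an extrapolation of
#' the joint fit to a predicted risk of one half. Also returns a
#' decile-of-risk table of observed vs expected counts for calibration plots.
#'
#' @inheritParams detection_rate_at_fpr
#' @param conf confidence level for Wald intervals.
#' @return object of class `calibration_fit`: list with `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `bin_table`, `degenerate`.
#' @export
calibration_fit <- function(risks, labels, conf = 0.95) {
  labels <- check_two_classes(labels)
  eps <- 1e-9
  if (any(risks <= 0 | risks >= 1)) {
    warning("risks at or outside (0, 1) clipped to [1e-9, 1 - 1e-9] for the logit")
  }
  lr <- logit(pmin(pmax(risks, eps), 1 - eps))
  degenerate <- stats::var(lr) < 1e-12
  if (degenerate) {
    warning("constant predicted risk: calibration slope is unidentifiable")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          slope_ci = c(NA_real_, NA_real_),
                          intercept_ci = c(NA_real_, NA_real_),
                          bin_table = NULL, degenerate = TRUE),
                     class = "calibration_fit"))
  }
  fit <- stats::glm(labels ~ lr, family = stats::binomial())
  fit0 <- stats::glm(labels ~ 1 + offset(lr), family = stats::binomial())
  co <- c(stats::coef(fit0)[1], stats::coef(fit)[2])
  se <- c(sqrt(stats::vcov(fit0)[1, 1]), sqrt(stats::vcov(fit)[2, 2]))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  qs <- unique(stats::quantile(risks, probs = seq(0, 1, by = 0.1), type = 7))
  bins <- cut(risks, breaks = qs, include.lowest = TRUE)
  bin_table <- data.frame(
    bin = levels(bins),
    n = as.vector(table(bins)),
    expected = as.vector(tapply(risks, bins, sum)),
    observed = as.vector(tapply(as.numeric(labels), bins, sum)),
    mean_risk = as.vector(tapply(risks, bins, mean))
  )
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 slope_ci = c(lower = co[2] - zq * se[2], upper = co[2] + zq * se[2]),
                 intercept_ci = c(lower = co[1] - zq * se[1], upper = co[1] + zq * se[1]),
                 bin_table = bin_table, degenerate = FALSE),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Calibration fit: degenerate (constant predicted risk)\n")
  } else {
    cat(sprintf("Calibration slope %.4f (%.4f to %.4f), intercept %.4f (%.4f to %.4f)\n",
                x$slope, x$slope_ci[1], x$slope_ci[2],
                x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  }
  invisible(x)
}

#' McNemar comparison of two screening methods at a fixed false-positive rate
#'
#' Each method is thresholded at its own `fpr` on the control distribution;
#' among true cases, the discordant detections form McNemar's test: exact
#' binomial when the discordant total is below `exact_below`, otherwise the
#' chi-square form with continuity correction.
#'
#' @param risks_a,risks_b risks from the two methods on the same records.
#' @inheritParams detection_rate_at_fpr
#' @param exact_below use the exact binomial test when `b + c` is below this.
#' @return list with `detected_a`, `detected_b`, `discordant` (b, c),
#'   `p_value`, `method`.
#' @export
mcnemar_fixed_fpr <- function(risks_a, risks_b, labels, fpr = 0.10,
                              exact_below = 25) {
  labels <- check_two_classes(labels)
  stopifnot(length(risks_a) == length(labels), length(risks_b) == length(labels))
  ta <- fpr_threshold(risks_a, labels, fpr)
  tb <- fpr_threshold(risks_b, labels, fpr)
  fa <- risks_a[labels] >= ta
  fb <- risks_b[labels] >= tb
  b <- sum(fa & !fb)
  c_ <- sum(!fa & fb)
  if (b + c_ == 0) {
    p <- 1
    method <- "exact binomial"
  } else if (b + c_ < exact_below) {
    p <- stats::binom.test(b, b + c_, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    p <- stats::mcnemar.test(matrix(c(sum(fa & fb), c_, b, sum(!fa & !fb)), 2, 2),
                             correct = TRUE)$p.value
    method <- "chi-square with continuity correction"
  }
  list(detected_a = sum(fa), detected_b = sum(fb), n_cases = sum(labels),
       discordant = c(a_only = b, b_only = c_), p_value = p, method = method)
}

#' Table of discrimination results for nested biomarker combinations
#'
#' Applies [roc_auc()] and [detection_rate_at_fpr()] to each risk column of a
#' screened cohort for each outcome definition, mirroring the layout of a
#' validation study's performance table.
#'
#' @param risk_table data.frame with one risk column per screening method.
#' @param outcome_labels named list of logical outcome vectors (one per
#'   outcome definition).
#' @param fpr fixed false-positive rate.
#' @return data.frame with one row per (method, outcome).
#' @export
evaluate_methods <- function(risk_table, outcome_labels, fpr = 0.10) {
  out <- list()
  for (m in names(risk_table)) {
    for (o in names(outcome_labels)) {
      keep <- !is.na(outcome_labels[[o]])
      ev <- detection_rate_at_fpr(risk_table[[m]][keep], outcome_labels[[o]][keep], fpr)
      au <- roc_auc(risk_table[[m]][keep], outcome_labels[[o]][keep])
      out[[length(out) + 1L]] <- data.frame(
        method = m, outcome = o, n_cases = ev$n_cases, n_controls = ev$n_controls,
        auc = au$auc, auc_lo = au$auc_ci[1], auc_hi = au$auc_ci[2],
        dr = ev$dr, dr_lo = ev$dr_ci[1], dr_hi = ev$dr_ci[2],
        threshold = ev$threshold
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
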