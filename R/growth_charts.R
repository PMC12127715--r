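#' Birth-weight charts: Z-scores and percentile cut-offs
#'
#' Birth weight is modelled on the natural-log scale: a chart supplies the
#' expected log weight and its standard deviation as smooth functions of
#' gestational age (GA) at delivery, and the Z-score of an observed weight is
#' `(log(weight) - mean_log_weight(ga)) / sd_log_weight(ga)`. Percentile
#' cut-offs (10th, 3rd, ...) are constant-Z contours of the chart.
#'
#' The default chart shipped with the package is a synthetic stand-in with a
#' published-style shape (cubic median curve on the log scale, linearly
#' tapering SD), anchored so that a reference screening population has its
#' median birth weight at its median gestational age at delivery. It is not a
#' transcription of any published chart; all chart parameters are
#' configuration, so a different parameterization can be substituted.
#'
#' @param mean_coef numeric vector of polynomial coefficients (intercept
#'   first) for mean log weight (grams, natural log) as a function of GA in
#'   weeks.
#' @param sd_coef numeric vector of polynomial coefficients for the SD of log
#'   weight as a function of GA in weeks.
#' @param ga_support closed GA interval (weeks) on which the chart is defined.
#' @return an object of class `weight_chart`.
#' @examples
#' ch <- default_weight_chart()
#' bw_zscore(3275, 39.5, ch)
#' @export
weight_chart <- function(mean_coef, sd_coef, ga_support = c(24, 43)) {
  stopifnot(is.numeric(mean_coef), length(mean_coef) >= 1,
            is.numeric(sd_coef), length(sd_coef) >= 1,
            length(ga_support) == 2, ga_support[1] < ga_support[2])
  chart <- structure(
    list(mean_coef = as.numeric(mean_coef),
         sd_coef = as.numeric(sd_coef),
         ga_support = as.numeric(ga_support)),
    class = "weight_chart"
  )
  # validate invariants on a fine grid
  gg <- seq(ga_support[1], ga_support[2], length.out = 2001)
  mu <- chart_mean_log(chart, gg)
  if (any(diff(mu) <= 0)) {
    stop("invalid weight chart: mean log weight is not strictly increasing over ga_support")
  }
  if (any(chart_sd_log(chart, gg) <= 0)) {
    stop("invalid weight chart: sd of log weight is not strictly positive over ga_support")
  }
  chart
}

polyval <- function(coef, x) {
  # coef[1] + coef[2]*x + ...
  out <- rep(0, length(x))
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

chart_mean_log <- function(chart, ga) polyval(chart$mean_coef, ga)
chart_sd_log <- function(chart, ga) polyval(chart$sd_coef, ga)

check_ga_support <- function(ga, chart) {
  lo <- chart$ga_support[1]; hi <- chart$ga_support[2]
  if (any(ga < lo)) stop(sprintf("gestational age %.4g below chart support lower bound %.4g", min(ga), lo))
  if (any(ga > hi)) stop(sprintf("gestational age %.4g above chart support upper bound %.4g", max(ga), hi))
  invisible(TRUE)
}

#' Default synthetic birth-weight chart
#'
#' See [weight_chart()] for the chart model and the provenance of the default
#' parameterization (a synthetic stand-in, not a transcription of a published
#' chart).
#'
#' @return a `weight_chart`.
#' @export
default_weight_chart <- function() {
  weight_chart(
    mean_coef = .default_chart_mean_coef,
    sd_coef = c(0.165 + 0.0015 * 24, -0.0015),
    ga_support = c(24, 43)
  )
}

#' Birth-weight Z-score
#'
#' @param weight_g birth weight in grams (> 0).
#' @param ga gestational age at delivery in decimal weeks, inside the chart
#'   support.
#' @param chart a [weight_chart()].
#' @return Z-score(s) on the chart's log-weight scale.
#' @export
bw_zscore <- function(weight_g, ga, chart = default_weight_chart()) {
  stopifnot(inherits(chart, "weight_chart"))
  if (any(weight_g <= 0)) stop("birth weight must be positive")
  check_ga_support(ga, chart)
  (log(weight_g) - chart_mean_log(chart, ga)) / chart_sd_log(chart, ga)
}

#' Weight at a given Z-score (chart quantile function)
#'
#' Inverse of [bw_zscore()] in the weight argument.
#'
#' @inheritParams bw_zscore
#' @param z Z-score(s).
#' @return weight in grams.
#' @export
chart_weight <- function(z, ga, chart = default_weight_chart()) {
  stopifnot(inherits(chart, "weight_chart"))
  check_ga_support(ga, chart)
  exp(chart_mean_log(chart, ga) + z * chart_sd_log(chart, ga))
}

#' Convert a percentile to its Z-score cut-off
#'
#' @param p percentile as a fraction in (0, 1), e.g. `0.10` for the 10th
#'   percentile.
#' @return the standard-normal inverse CDF of `p`.
#' @export
percentile_to_z <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("percentile must lie strictly inside (0, 1)")
  stats::qnorm(p)
}

#' Label a neonate as small-for-gestational-age
#'
#' TRUE iff the birth-weight Z-score lies strictly below the Z cut-off of the
#' `p`-th percentile. A weight exactly at the percentile is not SGA.
#'
#' @inheritParams bw_zscore
#' @param p percentile cut-off as a fraction in (0, 1).
#' @return logical vector.
#' @export
sga_label <- function(weight_g, ga, p, chart = default_weight_chart()) {
  bw_zscore(weight_g, ga, chart) < percentile_to_z(p)
}

#' @export
print.weight_chart <- function(x, ...) {
  cat("Birth-weight chart (log-scale)\n")
  cat(sprintf("  GA support: [%.1f, %.1f] weeks\n", x$ga_support[1], x$ga_support[2]))
  anchors <- c(28, 32, 36, 40)
  w <- round(exp(chart_mean_log(x, anchors)))
  cat("  median weight:", paste(sprintf("%dw: %dg", anchors, w), collapse = ", "), "\n")
  invisible(x)
}
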