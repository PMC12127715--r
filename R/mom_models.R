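#' Biomarker MoM conversion and likelihoods
#'
#' Raw first-trimester biomarker measurements (uterine artery pulsatility
#' index UtA-PI, serum PAPP-A, serum PlGF) are normalized to multiples of the
#' median (MoM): the measured value divided by the median expected for a woman
#' with the same characteristics. The expected median is modelled on the
#' log10 scale as a reference value plus additive covariate terms
#' ("MoM regression"). Conditional on the pregnancy outcome -- gestational age
#' at delivery `g` and birth-weight Z-score `z` -- log10 MoM is Gaussian with
#' a mean given by a continuous piecewise-planar ("folded plane") surface
#' `mu(g, z)` that is zero for unaffected term pregnancies (`g >= g0`,
#' `z >= z0`) and tilts linearly as delivery becomes earlier and the neonate
#' smaller.
#'
#' @name mom_models
NULL

# ---------------------------------------------------------------------------
# MoM regressions

#' Construct a MoM regression
#'
#' @param biomarker one of `"utapi"`, `"pappa"`, `"plgf"`.
#' @param reference_log10 expected log10 value at reference covariates.
#' @param terms named list of term definitions. Each element is a list with a
#'   `covariate` (column name in the maternal profile), an optional `center`
#'   subtracted before multiplying (for continuous covariates), an optional
#'   `level` the covariate must equal (for categorical covariates), and a
#'   `coef` additive effect on log10 expected value.
#' @return object of class `mom_regression`.
#' @export
mom_regression <- function(biomarker, reference_log10, terms = list()) {
  stopifnot(is.character(biomarker), length(biomarker) == 1,
            is.numeric(reference_log10), length(reference_log10) == 1)
  for (tm in terms) {
    if (is.null(tm$covariate) || is.null(tm$coef)) {
      stop("each MoM regression term needs a 'covariate' and a 'coef'")
    }
  }
  structure(list(biomarker = biomarker,
                 reference_log10 = reference_log10,
                 terms = terms),
            class = "mom_regression")
}

term_value <- function(tm, profile) {
  cov <- tm$covariate
  if (!cov %in% names(profile)) {
    stop(sprintf("MoM regression requires covariate '%s' missing from the profile", cov))
  }
  x <- profile[[cov]]
  if (!is.null(tm$level)) {
    v <- as.numeric(x == tm$level)
  } else if (is.logical(x)) {
    v <- as.numeric(x)
  } else {
    v <- as.numeric(x) - (tm$center %||% 0)
  }
  if (anyNA(v)) {
    stop(sprintf("MoM regression covariate '%s' has missing values", cov))
  }
  v * tm$coef
}

#' Expected log10 biomarker value for a maternal profile
#'
#' Reference log10 value plus the sum of the regression's covariate terms.
#'
#' @param profile a maternal profile: one-row data.frame (or a multi-row
#'   data.frame for vectorized evaluation).
#' @param reg a [mom_regression()].
#' @return numeric vector of expected log10 values.
#' @export
expected_log10 <- function(profile, reg) {
  stopifnot(inherits(reg, "mom_regression"))
  out <- rep(reg$reference_log10, max(1L, nrow(profile)))
  for (tm in reg$terms) out <- out + term_value(tm, profile)
  out
}

#' Convert a raw biomarker value to a MoM
#'
#' @param raw_value measured value in the biomarker's natural units (> 0).
#' @inheritParams expected_log10
#' @return MoM values (dimensionless).
#' @export
to_mom <- function(raw_value, profile, reg) {
  if (any(raw_value <= 0, na.rm = TRUE)) stop("raw biomarker values must be positive")
  raw_value / 10^expected_log10(profile, reg)
}

# ---------------------------------------------------------------------------
# Folded-plane likelihoods

#' Construct a folded-plane likelihood for log10 MoM
#'
#' The conditional mean of log10 MoM is
#' `mu(g, z) = slope_g * min(g - g0, 0) + slope_z * min(z - z0, 0)`,
#' i.e. zero at and beyond the knot `(g0, z0)` (unaffected term pregnancies
#' have expected MoM 1) and planar below it; the surface is continuous
#' everywhere. `sigma` is the SD of log10 MoM.
#'
#' @param biomarker biomarker name.
#' @param slope_g change in mean log10 MoM per week of `g` below `g0`
#'   (negative slope means the MoM rises as delivery gets earlier).
#' @param slope_z change per unit of `z` below `z0`.
#' @param sigma SD of log10 MoM (> 0).
#' @param g0,z0 knot location; defaults 40 weeks and Z = 0.
#' @return object of class `likelihood_plane`.
#' @export
likelihood_plane <- function(biomarker, slope_g, slope_z, sigma,
                             g0 = 40, z0 = 0) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  structure(list(biomarker = biomarker, slope_g = slope_g, slope_z = slope_z,
                 sigma = sigma, g0 = g0, z0 = z0),
            class = "likelihood_plane")
}

#' Folded-plane mean surface
#'
#' @param g gestational age at delivery (weeks).
#' @param z birth-weight Z-score.
#' @param plane a [likelihood_plane()].
#' @return mean log10 MoM at `(g, z)`; zero when `g >= g0` and `z >= z0`.
#' @export
plane_mu <- function(g, z, plane) {
  plane$slope_g * pmin(g - plane$g0, 0) + plane$slope_z * pmin(z - plane$z0, 0)
}

#' Gaussian log-likelihood of an observed log10 MoM given the outcome
#'
#' @param log10mom observed log10 MoM.
#' @inheritParams plane_mu
#' @return log density.
#' @export
log_likelihood <- function(log10mom, g, z, plane) {
  stats::dnorm(log10mom, mean = plane_mu(g, z, plane), sd = plane$sigma, log = TRUE)
}

#' @export
print.likelihood_plane <- function(x, ...) {
  cat(sprintf("Folded-plane likelihood for %s: mu = %+.4f*(g-%g)_- %+.4f*(z-%g)_-, sigma = %.3f\n",
              x$biomarker, x$slope_g, x$g0, x$slope_z, x$z0, x$sigma))
  invisible(x)
}
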