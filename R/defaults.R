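# Frozen default parameterization.
#
# All numbers below are package defaults, not transcriptions of published
# model coefficients: the MoM regressions, likelihood planes and maternal
# effect maps are synthetic stand-ins with field-realistic signs and
# magnitudes, and the prior baseline is the solution of the generator
# calibration (see calibrate_generator) against the reference cohort's
# printed outcome incidences.

# cubic median curve for the synthetic birth-weight chart, natural-log grams;
# intercept carries the anchor adjustment that centres the reference cohort's
# median birth weight (see data-raw note in the methods vignette)
.default_chart_mean_coef <- c(2.45287962072 - 0.017755,
                              0.148305633748, 0.0022043993466, -5.83453414631e-05)

# unscaled maternal effect shapes on mean GA at delivery (weeks) and
# birth-weight Z; scaled by the calibrated (lam_g, lam_z, kappa) below
.effect_shape_g <- c(
  nulliparous = 0.0, smoker = -0.10, chronic_htn = -3.6, diabetes = -1.0,
  sle_aps = -4.2, conception_oi = -0.3, conception_ivf = -0.5,
  prev_pe = -2.2, prev_sga = -0.3, prev_stillbirth = -3.0
)
.effect_shape_z <- c(
  nulliparous = -0.30, smoker = -0.55, chronic_htn = -1.80, diabetes = 0.30,
  sle_aps = -2.20, conception_oi = -0.15, conception_ivf = -0.25,
  prev_pe = -0.30, prev_sga = -1.10, prev_stillbirth = -1.60
)

# calibrated generator solution (deterministic re-solve available through
# calibrate_generator(); shipped here so the risk engine works out of the box
# and as the solver's warm start)
.calibrated_solution <- list(
  sd_g = 1.3728273928, rho = 0.0233240197,
  lam_g = 1.7901306438, lam_z = 2.3139490574, kappa = -0.3572359523,
  mean_g = 39.6798734551, mean_z = 0.2951358093, sd_z = 0.6673626088
)

# reference-cohort outcome targets: proportions of 35170 pregnancies
.default_targets <- list(
  sga10 = 5092 / 35170,
  sga3 = 2108 / 35170,
  sga10_pre37 = 707 / 35170,
  sga3_pre37 = 473 / 35170,
  sga10_pre32 = 140 / 35170,
  sga3_pre32 = 108 / 35170,
  preterm = 0.06,
  median_ga = 39.5
)

# pre-eclampsia co-label targets (counts from the reference cohort)
.default_pe_targets <- list(
  overall = 655 / 35170,
  preterm = 211 / 35170,
  preterm_sga = 136 / 35170,
  term = 444 / 35170,
  term_sga = 99 / 35170
)

# nested biomarker availability: PAPP-A for all, UtA-PI for a subset,
# PlGF for a subset of those
.default_missingness <- c(utapi = 17862 / 35170, plgf = 9775 / 35170)

.default_planes <- function() {
  # knots below term/mild-smallness keep the population median MoM near 1
  # while concentrating biomarker signal in clinically small/preterm outcomes
  list(
    utapi = likelihood_plane("utapi", slope_g = -0.030, slope_z = -0.065,
                             sigma = 0.12, g0 = 37, z0 = -1.2),
    pappa = likelihood_plane("pappa", slope_g = 0.018, slope_z = 0.060,
                             sigma = 0.26, g0 = 37, z0 = -1),
    plgf = likelihood_plane("plgf", slope_g = 0.045, slope_z = 0.050,
                            sigma = 0.16, g0 = 37, z0 = -1)
  )
}

.default_mom_regressions <- function() {
  list(
    utapi = mom_regression(
      "utapi", reference_log10 = log10(1.70),
      terms = list(
        list(covariate = "ga_at_screen", center = 12, coef = -0.022),
        list(covariate = "weight", center = 69, coef = -0.0015),
        list(covariate = "race", level = "Black", coef = 0.02),
        list(covariate = "smoker", coef = -0.010)
      )
    ),
    pappa = mom_regression(
      "pappa", reference_log10 = log10(3.0),
      terms = list(
        list(covariate = "ga_at_screen", center = 12, coef = 0.110),
        list(covariate = "weight", center = 69, coef = -0.0080),
        list(covariate = "race", level = "Black", coef = 0.180),
        list(covariate = "race", level = "South Asian", coef = -0.050),
        list(covariate = "race", level = "East Asian", coef = 0.070),
        list(covariate = "smoker", coef = -0.080),
        list(covariate = "conception", level = "ivf", coef = -0.120),
        list(covariate = "conception", level = "ovulation_induction", coef = -0.050),
        list(covariate = "diabetes", coef = -0.060)
      )
    ),
    plgf = mom_regression(
      "plgf", reference_log10 = log10(38),
      terms = list(
        list(covariate = "ga_at_screen", center = 12, coef = 0.090),
        list(covariate = "weight", center = 69, coef = -0.0040),
        list(covariate = "race", level = "Black", coef = 0.160),
        list(covariate = "smoker", coef = 0.130),
        list(covariate = "conception", level = "ivf", coef = -0.050),
        list(covariate = "diabetes", coef = -0.030)
      )
    )
  )
}

# Table-style maternal marginals of the reference population
.default_maternal_marginals <- list(
  age = list(median = 32.7, iqr = c(29.0, 36.2), range = c(16, 55)),
  weight = list(median = 63.5, iqr = c(57.0, 72.5), range = c(35, 200)),
  height = list(median = 164, iqr = c(160, 168), range = c(130, 200)),
  race = c("White" = 34884, "Black" = 78, "South Asian" = 7,
           "East Asian" = 19, "Mixed or other" = 182) / 35170,
  conception = c(natural = 31885, ovulation_induction = 375, ivf = 2910) / 35170,
  smoker = 4081 / 35170,
  chronic_htn = 389 / 35170,
  diabetes = 261 / 35170,
  sle_aps = 135 / 35170,
  nulliparous = 18960 / 35170,
  # conditional on parous
  prev_pe = 377 / (35170 - 18960),
  prev_sga = 934 / (35170 - 18960),
  prev_stillbirth = 45 / (35170 - 18960),
  interpregnancy_interval = list(median = 3, iqr = c(2.0, 4.9), range = c(0.3, 25)),
  ga_last_delivery = list(median = 39.2, iqr = c(38.6, 40.0), range = c(24, 43)),
  ga_at_screen = list(range = c(11.0, 13 + 6 / 7))
)
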