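test_that("expected log10 is the reference plus additive terms", {
  reg <- mom_regression("pappa", reference_log10 = 0.2,
                        terms = list(list(covariate = "smoker", coef = -0.05)))
  prof <- toy_profile()
  expect_equal(expected_log10(prof, reg), 0.2)
  prof$smoker <- TRUE
  expect_equal(expected_log10(prof, reg), 0.15)
  # three-term hand summation
  reg3 <- mom_regression("pappa", reference_log10 = 0.3, terms = list(
    list(covariate = "weight", center = 69, coef = -0.008),
    list(covariate = "race", level = "Black", coef = 0.18),
    list(covariate = "smoker", coef = -0.08)
  ))
  prof3 <- toy_profile(smoker = TRUE)
  prof3$weight <- 80; prof3$race <- "Black"
  expect_equal(expected_log10(prof3, reg3),
               0.3 + (80 - 69) * -0.008 + 0.18 - 0.08, tolerance = 1e-12)
})

test_that("missing covariates raise a named error", {
  reg <- mom_regression("plgf", 1.5, terms = list(list(covariate = "bmi", coef = 0.1)))
  expect_error(expected_log10(toy_profile(), reg), "'bmi'")
})

test_that("MoM is the measured value over the expected median", {
  reg <- mom_regression("utapi", log10(1.7),
                        terms = list(list(covariate = "smoker", coef = -0.01)))
  prof <- toy_profile()
  expect_equal(to_mom(1.7, prof, reg), 1.0)
  expect_equal(to_mom(3.4, prof, reg), 2.0)
  expect_error(to_mom(-1, prof, reg), "positive")
})

test_that("a cohort generated from the MoM model has median MoM near 1", {
  params <- default_params()
  prof <- sample_maternal(10000, seed = 5)
  outc <- sample_outcome(prof, params, seed = 6)
  bio <- sample_biomarkers(outc, prof, params, seed = 7,
                           missingness = c(utapi = 1, plgf = 1))
  for (b in c("utapi", "pappa", "plgf")) {
    mom <- to_mom(bio[[b]], prof, params$mom_regressions[[b]])
    expect_gt(median(mom), 0.97)
    expect_lt(median(mom), 1.03)
  }
})

test_that("folded plane is flat at zero beyond the knot and continuous", {
  pl <- likelihood_plane("utapi", slope_g = -0.01, slope_z = -0.03, sigma = 0.12)
  expect_equal(plane_mu(c(40, 41, 43), c(0, 1, 2), pl), c(0, 0, 0))
  # continuity across the knot
  eps <- 1e-9
  expect_equal(plane_mu(40 - eps, 0, pl), 0, tolerance = 1e-10)
  expect_equal(plane_mu(40, -eps, pl), 0, tolerance = 1e-10)
  # tilts in the configured direction below the knot
  expect_gt(plane_mu(35, -2, pl), plane_mu(38, -1, pl))
})

test_that("log-likelihood is the closed-form Gaussian density", {
  pl <- likelihood_plane("plgf", slope_g = 0.026, slope_z = 0.04, sigma = 0.16)
  # at the mode the density is 1/(sigma sqrt(2 pi))
  mode_ll <- log(1 / (0.16 * sqrt(2 * pi)))
  expect_equal(log_likelihood(plane_mu(33, -2, pl), 33, -2, pl), mode_ll)
  expect_equal(log_likelihood(0, 41, 1, pl), mode_ll)   # mu = 0 beyond the knot
  expect_equal(log_likelihood(0.21, 35, -1.2, pl),
               dnorm(0.21, pl$slope_g * (35 - 40) + pl$slope_z * (-1.2), 0.16, log = TRUE),
               tolerance = 1e-12)
})

test_that("likelihood integrates to 1 over log10 MoM", {
  pl <- likelihood_plane("pappa", slope_g = 0.012, slope_z = 0.06, sigma = 0.26)
  for (gz in list(c(40, 0), c(30, -3), c(36.5, 1.2))) {
    I <- integrate(function(v) exp(log_likelihood(v, gz[1], gz[2], pl)),
                   -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
})

test_that("MoM directionality: earlier and smaller raises UtA-PI, lowers PAPP-A and PlGF", {
  planes <- default_params()$planes
  gs <- seq(36, 25, by = -1)   # below every knot
  mu_u <- plane_mu(gs, -2, planes$utapi)
  mu_p <- plane_mu(gs, -2, planes$pappa)
  mu_pl <- plane_mu(gs, -2, planes$plgf)
  expect_true(all(diff(mu_u) > 0))    # UtA-PI MoM increases as g decreases
  expect_true(all(diff(mu_p) < 0))
  expect_true(all(diff(mu_pl) < 0))
  # smaller neonate at fixed GA
  expect_gt(plane_mu(39, -3, planes$utapi), plane_mu(39, -2, planes$utapi))
  expect_lt(plane_mu(39, -3, planes$plgf), plane_mu(39, -2, planes$plgf))
})
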