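test_that("maternal sampling is reproducible and matches marginals", {
  p1 <- sample_maternal(5000, seed = 42)
  p2 <- sample_maternal(5000, seed = 42)
  expect_identical(p1, p2)
  p3 <- sample_maternal(5000, seed = 43)
  expect_false(identical(p1$age, p3$age))
  # parous-only fields are absent (NA) exactly for nulliparous women
  nulli <- p1$parity == "nulliparous"
  expect_true(all(is.na(p1$interpregnancy_interval[nulli])))
  expect_true(all(!is.na(p1$interpregnancy_interval[!nulli])))
  expect_true(all(!p1$prev_sga[nulli]))
  expect_true(all(p1$ga_at_screen >= 11 & p1$ga_at_screen <= 13 + 6 / 7))
})

test_that("category proportions must sum to one", {
  m <- sgascreen:::.default_maternal_marginals
  m$race <- c(m$race[-1], White = 0.5)
  expect_error(generator_config(marginals = m), "sum to 1")
})

test_that("outcome sampling respects truncation and chart consistency", {
  params <- toy_params()
  prof <- toy_profile(n = 500)
  outc <- sample_outcome(prof, params, seed = 3)
  expect_true(all(outc$ga_delivery >= 24 & outc$ga_delivery <= 43))
  # weight is the chart inverse of (z, g): labels recompute exactly
  z2 <- bw_zscore(outc$birth_weight, outc$ga_delivery)
  expect_equal(z2, outc$bw_z, tolerance = 1e-9)
})

test_that("with zero effects, zero mean z and no correlation, SGA10 is 10% at any GA", {
  params <- crp_params(mean_g = 39.5, mean_z = 0, sd_g = 2, sd_z = 1, rho = 0,
                       grid = coarse_grid())
  prof <- toy_profile(n = 40000)
  outc <- sample_outcome(prof, params, seed = 8)
  sga10 <- outc$bw_z < percentile_to_z(0.10)
  expect_lt(abs(mean(sga10) - 0.10), 0.005)        # ~3 binomial SEs at n=40000
  early <- outc$ga_delivery < 38
  expect_lt(abs(mean(sga10[early]) - mean(sga10[!early])), 0.012)
})

test_that("biomarker sampling collapses to the plane mean when sigma shrinks", {
  params <- toy_params()
  params$planes <- lapply(params$planes, function(pl) {
    pl$sigma <- 1e-12; pl
  })
  prof <- toy_profile(n = 50)
  outc <- sample_outcome(prof, params, seed = 4)
  bio <- sample_biomarkers(outc, prof, params, seed = 5,
                           missingness = c(utapi = 1, plgf = 1))
  for (b in c("utapi", "pappa", "plgf")) {
    l10 <- log10(to_mom(bio[[b]], prof, params$mom_regressions[[b]]))
    expect_equal(l10, plane_mu(outc$ga_delivery, outc$bw_z, params$planes[[b]]),
                 tolerance = 1e-7)
  }
})

test_that("biomarker availability is nested with the configured fractions", {
  params <- default_params(grid = coarse_grid())
  coh <- simulate_cohort(generator_config(n = 20000, seed = 12, params = params))
  expect_true(all(!is.na(coh$pappa)))
  expect_true(all(!is.na(coh$utapi[!is.na(coh$plgf)])))   # PlGF nested in UtA-PI
  expect_equal(mean(!is.na(coh$utapi)), 17862 / 35170, tolerance = 0.015)
  expect_equal(mean(!is.na(coh$plgf)), 9775 / 35170, tolerance = 0.015)
})

test_that("calibration reproduces the reference incidences analytically", {
  tg <- sgascreen:::.default_targets
  params <- calibrate_generator()
  ach <- attr(params, "achieved")
  expect_equal(ach$sga10, tg$sga10, tolerance = 1e-6)
  expect_equal(ach$sga3, tg$sga3, tolerance = 1e-6)
  expect_lt(max(abs(attr(params, "residuals"))), 0.05)
  # analytic joint probabilities within +-0.001 absolute of the targets
  expect_lt(abs(ach$sga10_pre37 - tg$sga10_pre37), 1e-3)
  expect_lt(abs(ach$sga10_pre32 - tg$sga10_pre32), 1e-3)
})

test_that("infeasible nesting of targets is rejected", {
  tg <- sgascreen:::.default_targets
  tg$sga10_pre37 <- 0.2     # joint above the marginal
  expect_error(calibrate_generator(targets = tg), "infeasible")
})

test_that("PE rates are infeasible when targets exceed the available mass", {
  params <- default_params()
  pe <- sgascreen:::.default_pe_targets
  pe$preterm_sga <- 0.5
  expect_error(derive_pe_rates(params, pe), "infeasible")
})

test_that("identical seeds give identical cohorts; stages use distinct streams", {
  cfg <- generator_config(n = 300, seed = 77, params = default_params(grid = coarse_grid()))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  s <- seed_streams(77)
  expect_length(unique(s), 5)
})

test_that("generated Z-scores are close to standard normal", {
  params <- default_params(grid = coarse_grid())
  coh <- simulate_cohort(generator_config(n = 10000, seed = 21, params = params))
  ks <- suppressWarnings(ks.test(coh$bw_z, "pnorm"))$statistic
  expect_lt(ks, 0.15)
  expect_equal(sd(coh$bw_z), 1, tolerance = 0.1)
})
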