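test_that("prior density peaks at the shifted means and integrates to 1", {
  params <- toy_params()
  pr <- prior_density(toy_profile(), params)
  wg <- diff(pr$g[1:2]); wz <- diff(pr$z[1:2])
  peak <- which(pr$density == max(pr$density), arr.ind = TRUE)[1, ]
  expect_equal(pr$g[peak[1]], 39.5, tolerance = wg)
  expect_equal(pr$z[peak[2]], 0, tolerance = wz)
  expect_equal(sga_risk(pr, p = 1 - 1e-12, ga_cutoff = Inf), 1, tolerance = 1e-6)
  # a previous-SGA effect of (-1.0, -0.8) shifts the peak by exactly that much
  pr2 <- prior_density(toy_profile(prev_sga = TRUE), params)
  peak2 <- which(pr2$density == max(pr2$density), arr.ind = TRUE)[1, ]
  expect_equal(pr$g[peak[1]] - pr2$g[peak2[1]], 1.0, tolerance = 2 * wg)
  expect_equal(pr$z[peak[2]] - pr2$z[peak2[2]], 0.8, tolerance = 2 * wz)
})

test_that("prior rectangle mass matches a Monte-Carlo oracle", {
  params <- toy_params()
  pr <- prior_density(toy_profile(), params)
  grid_mass <- sga_risk(pr, 0.10, 37)
  set.seed(202)
  n <- 1e6
  e1 <- rnorm(n); e2 <- rnorm(n)
  g <- 39.5 + 2 * e1
  z <- 0 + 1 * (0.25 * e1 + sqrt(1 - 0.25^2) * e2)
  keep <- g >= 24 & g <= 43 & z >= -5 & z <= 5
  hits <- (z[keep] < qnorm(0.10)) & (g[keep] < 37)
  mc <- mean(hits)
  se <- sd(hits) / sqrt(sum(keep))
  expect_lt(abs(grid_mass - mc), 3 * se + 1e-6)
})

test_that("empty or flat likelihoods leave the prior unchanged", {
  params <- toy_params()
  pr <- prior_density(toy_profile(), params)
  expect_equal(posterior_update(pr, numeric(0), params$planes)$density,
               pr$density, tolerance = 1e-12)
  # mu identically 0 and log10 MoM = 0: constant likelihood cancels
  flat <- list(utapi = likelihood_plane("utapi", 0, 0, sigma = 0.2))
  up <- posterior_update(pr, c(utapi = 0), flat)
  expect_lt(max(abs(up$density - pr$density)), 1e-12)
})

test_that("posterior rectangle mass matches an importance-sampling oracle", {
  params <- toy_params(rho = 0.3)
  pr <- prior_density(toy_profile(), params)
  v <- 0.15   # elevated UtA-PI log10 MoM
  post <- posterior_update(pr, c(utapi = v), params$planes)
  grid_mass <- sga_risk(post, 0.10, 37)
  set.seed(77)
  n <- 1e6
  e1 <- rnorm(n); e2 <- rnorm(n)
  g <- 39.5 + 2 * e1
  z <- 0.3 * e1 + sqrt(1 - 0.09) * e2
  keep <- g >= 24 & g <= 43 & z >= -5 & z <= 5
  g <- g[keep]; z <- z[keep]
  w <- dnorm(v, plane_mu(g, z, params$planes$utapi), params$planes$utapi$sigma)
  w <- w / sum(w)
  hit <- (z < qnorm(0.10)) & (g < 37)
  is_est <- sum(w * hit)
  is_se <- sqrt(sum(w^2 * (hit - is_est)^2))
  expect_lt(abs(grid_mass - is_est), 3 * is_se + 1e-6)
})

test_that("risk is monotone in percentile, cut-off, and UtA-PI MoM", {
  params <- toy_params()
  pr <- prior_density(toy_profile(), params)
  post <- posterior_update(pr, c(utapi = 0.1), params$planes)
  expect_lte(sga_risk(post, 0.03, 37), sga_risk(post, 0.10, 37))
  expect_lte(sga_risk(post, 0.10, 32), sga_risk(post, 0.10, 37))
  expect_lte(sga_risk(post, 0.10, 37), sga_risk(post, 0.10, Inf))
  risks <- vapply(seq(-0.3, 0.3, length.out = 50), function(v) {
    sga_risk(posterior_update(pr, c(utapi = v), params$planes), 0.10, 37)
  }, numeric(1))
  expect_true(all(diff(risks) >= 0))
})

test_that("a symmetric prior with median percentile gives risk one half", {
  params <- crp_params(mean_g = 33.5, mean_z = 0, sd_g = 1.5, sd_z = 1, rho = 0,
                       grid = coarse_grid())
  pr <- prior_density(toy_profile()[, setdiff(names(toy_profile()), "prev_sga")], params)
  expect_equal(sga_risk(pr, 0.5, Inf), 0.5, tolerance = 1e-6)
})

test_that("screening is deterministic and composes prior with update", {
  params <- toy_params()
  rec <- toy_profile(smoker = TRUE)
  rec$utapi <- 1.9; rec$pappa <- 2.4; rec$plgf <- NA
  r1 <- screen_record(rec, params)
  r2 <- screen_record(rec, params)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "biomarkers_used"), "utapi+pappa")
  # no biomarkers: equals prior-only rectangle risk
  rec0 <- rec; rec0$utapi <- NA; rec0$pappa <- NA
  r0 <- screen_record(rec0, params)
  pr <- prior_density(rec0, params)
  expect_equal(unname(r0["p10_ga37"]), sga_risk(pr, 0.10, 37), tolerance = 1e-12)
})

test_that("vectorized cohort screening equals the per-record path", {
  params <- default_params(grid = coarse_grid())
  coh <- simulate_cohort(generator_config(n = 40, seed = 9, params = params))
  rv <- screen_cohort(coh, params)
  for (k in c(1, 13, 27, 40)) {
    rr <- screen_record(coh[k, ], params)
    expect_equal(as.numeric(rv[k, 1:4]), unname(rr[1:4]), tolerance = 1e-10)
  }
  # restricting biomarkers reproduces the nested combinations
  rv_mf <- screen_cohort(coh, params, use_biomarkers = character(0))
  expect_true(all(rv_mf$biomarkers_used == "none"))
  rr_mf <- screen_record(coh[5, ], params, use_biomarkers = character(0))
  expect_equal(as.numeric(rv_mf[5, 1:4]), unname(rr_mf[1:4]), tolerance = 1e-10)
})

test_that("halving the grid steps changes risks by less than 1e-4", {
  params <- default_params()
  params_fine <- default_params(grid = default_grid(g_step = 0.025, z_step = 0.01))
  rec <- toy_profile(smoker = TRUE)
  rec$utapi <- 2.1; rec$pappa <- 1.4; rec$plgf <- 18
  r <- screen_record(rec, params)
  rf <- screen_record(rec, params_fine)
  expect_lt(max(abs(r - rf)), 1e-4)
})

test_that("degenerate grids and underflow raise informative errors", {
  expect_error(posterior_grid(1:3, 1:3, matrix(0, 3, 3)), "underflow")
  params <- toy_params()
  pr <- prior_density(toy_profile(), params)
  expect_error(posterior_update(pr, c(nope = 0.1), params$planes), "nope")
})
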