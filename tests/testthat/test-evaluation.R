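test_that("detection rate at fixed FPR matches exhaustive threshold scans", {
  # interleaved cases among 100 distinct control values
  ctrl <- (1:100) / 101
  cases <- c(0.055, 0.35, 0.82, 0.905, 0.99)
  risks <- c(ctrl, cases)
  labels <- c(rep(FALSE, 100), rep(TRUE, 5))
  ev <- detection_rate_at_fpr(risks, labels, fpr = 0.10)
  expect_equal(ev$dr, dr_bruteforce(risks, labels, 0.10))
  expect_lte(ev$fpr_realized, 0.10)
  # property: agreement with the scan across random tied/untied inputs
  set.seed(31)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    r <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    l <- runif(n) < 0.3
    if (!any(l) || all(l)) next
    for (f in c(0.05, 0.10, 0.25)) {
      expect_equal(detection_rate_at_fpr(r, l, f)$dr, dr_bruteforce(r, l, f),
                   info = sprintf("case %d fpr %.2f", i, f))
    }
  }
})

test_that("degenerate detection-rate inputs behave per the threshold rule", {
  # perfectly separated risks detect everything
  r <- c(runif(50, 0, 0.4), runif(10, 0.6, 1))
  l <- rep(c(FALSE, TRUE), c(50, 10))
  expect_equal(detection_rate_at_fpr(r, l, 0.10)$dr, 1.0)
  # identical risks for everyone: nobody can be flagged within the FPR budget
  ev <- detection_rate_at_fpr(rep(0.2, 60), l, 0.10)
  expect_lte(ev$dr, 0.10)
  expect_error(detection_rate_at_fpr(runif(10), rep(TRUE, 10)), "both cases and controls")
})

test_that("AUC equals brute-force pair counting (incl. frozen example)", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  r <- c(runif(100, 0, 0.4), runif(20, 0.6, 1))
  l <- rep(c(FALSE, TRUE), c(100, 20))
  expect_equal(roc_auc(r, l)$auc, 1.0)
  set.seed(99)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    risks <- sample(seq(0, 1, 0.02), n, replace = TRUE)
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    au <- roc_auc(risks, labels)
    expect_equal(au$auc, auc_bruteforce(risks, labels), tolerance = 1e-12)
    expect_gte(au$auc, au$auc_ci[[1]])
    expect_lte(au$auc, au$auc_ci[[2]])
  }
})

test_that("AUC on label-independent risks is near one half", {
  set.seed(7)
  risks <- runif(20000)
  labels <- runif(20000) < 0.2
  expect_equal(roc_auc(risks, labels)$auc, 0.5, tolerance = 0.02)
})

test_that("self-calibrated risks give slope near 1 and intercept near 0", {
  set.seed(123)
  n <- 50000
  risk <- plogis(rnorm(n, -3.5, 1.2))
  y <- runif(n) < risk
  cf <- calibration_fit(risk, y)
  expect_gt(cf$slope, 0.9); expect_lt(cf$slope, 1.1)
  expect_gt(cf$intercept, -0.1); expect_lt(cf$intercept, 0.1)
  expect_true(cf$slope >= cf$slope_ci[[1]] && cf$slope <= cf$slope_ci[[2]])
})

test_that("calibration slope recovers a logit-scale distortion", {
  set.seed(124)
  n <- 50000
  eta <- rnorm(n, -3.5, 1.2)
  y <- runif(n) < plogis(eta)            # truth generated from eta
  distorted <- plogis(eta / 2)           # reported risks halve the logit
  cf <- calibration_fit(distorted, y)
  expect_equal(cf$slope, 2, tolerance = 0.1)
})

test_that("constant risks give a flagged degenerate calibration fit", {
  y <- rep(c(TRUE, FALSE), c(20, 80))
  expect_warning(cf <- calibration_fit(rep(0.2, 100), y), "unidentifiable")
  expect_true(cf$degenerate)
  expect_true(is.na(cf$slope))
})

test_that("McNemar comparison handles symmetric, identical and one-sided discordance", {
  set.seed(5)
  n <- 400
  labels <- rep(c(TRUE, FALSE), c(80, 320))
  r <- runif(n)
  # identical risk vectors: p = 1
  expect_equal(mcnemar_fixed_fpr(r, r, labels)$p_value, 1.0)
  # construct case flags directly via risk manipulation: 10 vs 0 discordant
  ra <- r
  rb <- r
  ta <- fpr_threshold(ra, labels, 0.10)
  det <- which(labels & ra >= ta)
  flip <- det[1:10]
  rb[flip] <- 0                      # method b misses 10 cases method a detects
  mc <- mcnemar_fixed_fpr(ra, rb, labels, 0.10)
  expect_equal(unname(mc$discordant["a_only"] - mc$discordant["b_only"]), 10)
  if (sum(mc$discordant) == 10) {
    expect_equal(mc$p_value, 2 * 0.5^10, tolerance = 1e-12)
  }
})

test_that("exact McNemar p-value for 10-vs-0 discordance is 2 * 0.5^10", {
  # direct check of the exact branch on constructed flags
  labels <- rep(TRUE, 40)
  labels <- c(labels, rep(FALSE, 160))
  ra <- c(rep(0.9, 40), runif(160, 0, 0.5))          # detects all cases
  rb <- c(rep(0.9, 30), rep(0.01, 10), runif(160, 0, 0.5))  # misses 10
  mc <- mcnemar_fixed_fpr(ra, rb, labels, fpr = 0.10)
  expect_identical(mc$method, "exact binomial")
  expect_equal(unname(mc$discordant), c(10, 0))
  expect_equal(mc$p_value, 2 * 0.5^10, tolerance = 1e-12)
})

test_that("DR at fixed FPR is invariant to strictly increasing transforms", {
  set.seed(17)
  r <- runif(300)
  l <- runif(300) < 0.25
  for (f in list(function(x) x^3, function(x) plogis(5 * x), function(x) exp(x))) {
    expect_equal(detection_rate_at_fpr(f(r), l, 0.10)$dr,
                 detection_rate_at_fpr(r, l, 0.10)$dr)
    expect_equal(roc_auc(f(r), l)$auc, roc_auc(r, l)$auc, tolerance = 1e-12)
  }
})
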