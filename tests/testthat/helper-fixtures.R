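# Shared fixtures: small deterministic objects used across test files.

# toy chart: median 3500 g at 40 weeks, constant log-SD 0.15
toy_chart <- function() {
  weight_chart(mean_coef = c(log(3500) - 40 * 0.05, 0.05),
               sd_coef = 0.15, ga_support = c(24, 43))
}

# coarse grid keeps unit tests fast; acceptance tests use the default grid
coarse_grid <- function() default_grid(g_step = 0.2, z_step = 0.05)

toy_params <- function(grid = coarse_grid(), rho = 0.25) {
  crp_params(mean_g = 39.5, mean_z = 0, sd_g = 2.0, sd_z = 1.0, rho = rho,
             effects_g = c(smoker = -0.5, prev_sga = -1.0),
             effects_z = c(smoker = -0.4, prev_sga = -0.8),
             grid = grid)
}

# minimal valid maternal profile
toy_profile <- function(n = 1, smoker = FALSE, prev_sga = FALSE) {
  data.frame(
    age = rep(32, n), weight = 69, height = 164, race = "White",
    smoker = smoker, conception = "natural",
    chronic_htn = FALSE, diabetes = FALSE, sle_aps = FALSE,
    parity = ifelse(prev_sga, "parous", "nulliparous"),
    prev_pe = FALSE, prev_sga = prev_sga, prev_stillbirth = FALSE,
    interpregnancy_interval = ifelse(prev_sga, 3, NA),
    ga_last_delivery = ifelse(prev_sga, 39, NA),
    ga_at_screen = 12.5,
    stringsAsFactors = FALSE
  )
}

# brute-force AUC by pair counting (independent oracle)
auc_bruteforce <- function(risks, labels) {
  cases <- risks[as.logical(labels)]
  ctrls <- risks[!as.logical(labels)]
  s <- 0
  for (x in cases) s <- s + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  s / (length(cases) * length(ctrls))
}

# brute-force detection rate at fixed FPR by exhaustive threshold scan
dr_bruteforce <- function(risks, labels, fpr = 0.10) {
  labels <- as.logical(labels)
  cand <- sort(unique(risks[!labels]))
  ok <- cand[vapply(cand, function(t) mean(risks[!labels] >= t) <= fpr, TRUE)]
  if (!length(ok)) {
    # no admissible control threshold: only risks above every control flag
    return(mean(risks[labels] > max(risks[!labels])))
  }
  t <- min(ok)
  mean(risks[labels] >= t)
}
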