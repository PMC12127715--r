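#' Competing-risks Bayes machinery
#'
#' The model treats the pregnancy outcome as a point in the
#' (gestational age at delivery `g`, birth-weight Z-score `z`) plane.
#' A-priori, `(g, z)` is bivariate Gaussian with means shifted additively by
#' maternal factors, truncated to the grid support. Each available biomarker
#' contributes a Gaussian likelihood for its observed log10 MoM whose mean is
#' a folded-plane function of `(g, z)`. The posterior is computed on a dense
#' rectangular grid, and the risk of delivering an SGA neonate below
#' percentile `p` before `ga_cutoff` weeks is the posterior mass of the
#' rectangle `{z < qnorm(p)} x {g < ga_cutoff}` (trapezoidal integration).
#'
#' @name risk_engine
NULL

grid_axes <- function(grid) {
  list(g = seq(grid$g_range[1], grid$g_range[2], by = grid$g_step),
       z = seq(grid$z_range[1], grid$z_range[2], by = grid$z_step))
}

trap_weights <- function(axis) {
  n <- length(axis)
  h <- axis[2] - axis[1]
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

# trapezoid weights for integrating a gridded function from axis[1] up to t,
# with linear interpolation inside the final partial cell
trap_weights_to <- function(axis, t) {
  n <- length(axis)
  h <- axis[2] - axis[1]
  if (t >= axis[n]) return(trap_weights(axis))
  w <- numeric(n)
  if (t <= axis[1]) return(w)
  i <- findInterval(t, axis)   # axis[i] <= t < axis[i+1]
  if (i >= 2) {
    w[seq_len(i)] <- h
    w[1] <- h / 2
    w[i] <- h / 2
  }
  u <- t - axis[i]
  if (u > 0) {
    w[i] <- w[i] + (u - u^2 / (2 * h))
    w[i + 1] <- w[i + 1] + u^2 / (2 * h)
  }
  w
}

#' Posterior grid container
#'
#' A discretized joint density over `(g, z)`, normalized so that its
#' trapezoidal integral over the grid is 1.
#'
#' @param g,z increasing grid axes.
#' @param density non-negative matrix, `length(g)` rows by `length(z)` columns.
#' @return object of class `posterior_grid`.
#' @export
posterior_grid <- function(g, z, density) {
  stopifnot(is.matrix(density), nrow(density) == length(g), ncol(density) == length(z))
  if (any(density < 0)) stop("posterior density must be non-negative")
  wg <- trap_weights(g); wz <- trap_weights(z)
  total <- drop(wg %*% density %*% wz)
  if (!is.finite(total) || total <= 0) {
    stop("posterior underflow: all grid mass vanished; accumulate in log space")
  }
  density <- density / total
  structure(list(g = g, z = z, density = density), class = "posterior_grid")
}

#' Prior joint density for one maternal profile
#'
#' Bivariate Gaussian over `(g, z)` with means `baseline + maternal effects`,
#' renormalized over the grid support (which truncates deliveries to the
#' chart's GA range).
#'
#' @param profile one-row data.frame of maternal covariates.
#' @param params a [crp_params()].
#' @return a [posterior_grid()].
#' @export
prior_density <- function(profile, params) {
  stopifnot(inherits(params, "crp_params"))
  sh <- maternal_shift(profile, params)
  if (nrow(sh) != 1) stop("prior_density expects a single profile; see screen_cohort for batches")
  ax <- grid_axes(params$grid)
  mg <- params$mean_g + sh$dg
  mz <- params$mean_z + sh$dz
  q <- -0.5 / (1 - params$rho^2)
  G <- (ax$g - mg) / params$sd_g
  Z <- (ax$z - mz) / params$sd_z
  lp <- q * (outer(G^2, rep(1, length(Z))) -
               2 * params$rho * outer(G, Z) +
               outer(rep(1, length(G)), Z^2))
  lp <- lp - max(lp)
  posterior_grid(ax$g, ax$z, exp(lp))
}

#' Bayes update of a posterior grid with available biomarker MoMs
#'
#' Multiplies the prior by the Gaussian likelihood of each supplied log10 MoM
#' (folded-plane mean) and renormalizes. Biomarkers absent from `log10moms`
#' are simply omitted, which is how nested biomarker availability (maternal
#' factors only, + UtA-PI, + PAPP-A, + PlGF) is handled. Accumulation is in
#' log space to avoid underflow for extreme MoMs.
#'
#' @param prior a [posterior_grid()].
#' @param log10moms named numeric vector of observed log10 MoM values; may be
#'   empty. Names must match names of `planes`.
#' @param planes named list of [likelihood_plane()] objects.
#' @return a [posterior_grid()].
#' @export
posterior_update <- function(prior, log10moms, planes) {
  stopifnot(inherits(prior, "posterior_grid"))
  log10moms <- log10moms[!is.na(log10moms)]
  if (!length(log10moms)) return(prior)
  miss <- setdiff(names(log10moms), names(planes))
  if (length(miss)) stop("no likelihood plane for biomarker(s): ", paste(miss, collapse = ", "))
  lp <- log(prior$density)
  for (b in names(log10moms)) {
    pl <- planes[[b]]
    mu <- outer(pmin(prior$g - pl$g0, 0) * pl$slope_g,
                pmin(prior$z - pl$z0, 0) * pl$slope_z, `+`)
    lp <- lp + stats::dnorm(log10moms[[b]], mean = mu, sd = pl$sigma, log = TRUE)
  }
  m <- max(lp)
  if (!is.finite(m)) {
    stop("posterior underflow: likelihood product vanished on the whole grid; accumulate in log space / check MoM values")
  }
  posterior_grid(prior$g, prior$z, exp(lp - m))
}

#' Rectangle risk from a posterior grid
#'
#' Posterior probability that the birth-weight Z-score lies below the `p`-th
#' percentile cut-off and delivery occurs before `ga_cutoff`.
#'
#' @param post a [posterior_grid()].
#' @param p birth-weight percentile as a fraction in (0, 1).
#' @param ga_cutoff gestational-age cut-off in weeks; `Inf` for any GA.
#' @return probability.
#' @export
sga_risk <- function(post, p, ga_cutoff = Inf) {
  stopifnot(inherits(post, "posterior_grid"))
  zc <- percentile_to_z(p)
  wg <- trap_weights_to(post$g, ga_cutoff)
  wz <- trap_weights_to(post$z, zc)
  num <- drop(wg %*% post$density %*% wz)
  den <- drop(trap_weights(post$g) %*% post$density %*% trap_weights(post$z))
  num / den
}

#' Default screening targets
#'
#' The four (percentile, GA cut-off) pairs reported in first-trimester SGA
#' screening studies: SGA below the 10th or 3rd percentile delivered before
#' 37 or 32 weeks.
#'
#' @return data.frame with columns `name`, `p`, `ga_cutoff`.
#' @export
sga_targets <- function() {
  data.frame(
    name = c("p10_ga37", "p10_ga32", "p3_ga37", "p3_ga32"),
    p = c(0.10, 0.10, 0.03, 0.03),
    ga_cutoff = c(37, 32, 37, 32),
    stringsAsFactors = FALSE
  )
}

#' Screen one pregnancy record
#'
#' Composes MoM conversion, the Bayes update with whatever biomarkers the
#' record carries, and the rectangle risk for each requested target.
#' Deterministic given the parameters.
#'
#' @param record one-row data.frame with the maternal covariates plus optional
#'   raw biomarker columns `utapi`, `pappa`, `plgf` (NA = not measured).
#' @param params a [crp_params()].
#' @param targets data.frame as returned by [sga_targets()].
#' @param use_biomarkers biomarkers the screener is allowed to use (risks for
#'   nested combinations are obtained by restricting this set).
#' @return named numeric vector of risks (one per target) with attribute
#'   `biomarkers_used`.
#' @export
screen_record <- function(record, params, targets = sga_targets(),
                          use_biomarkers = c("utapi", "pappa", "plgf")) {
  moms <- record_log10moms(record, params, use_biomarkers)
  post <- posterior_update(prior_density(record, params), moms, params$planes)
  risks <- vapply(seq_len(nrow(targets)),
                  function(i) sga_risk(post, targets$p[i], targets$ga_cutoff[i]),
                  numeric(1))
  names(risks) <- targets$name
  attr(risks, "biomarkers_used") <- paste(names(moms), collapse = "+")
  risks
}

record_log10moms <- function(record, params, use_biomarkers) {
  out <- numeric(0)
  for (b in intersect(use_biomarkers, names(params$mom_regressions))) {
    if (b %in% names(record) && !is.na(record[[b]])) {
      out[b] <- log10(to_mom(record[[b]], record, params$mom_regressions[[b]]))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Vectorized cohort screening

# Precomputed grid surfaces shared by all records.
engine_surfaces <- function(params) {
  ax <- grid_axes(params$grid)
  ng <- length(ax$g); nz <- length(ax$z)
  Gv <- rep(ax$g, times = nz)
  Zv <- rep(ax$z, each = ng)
  q <- -0.5 / (1 - params$rho^2)
  B <- q * (Gv^2 / params$sd_g^2 - 2 * params$rho * Gv * Zv / (params$sd_g * params$sd_z) +
              Zv^2 / params$sd_z^2)
  Fm <- list(B = B, G = Gv, Z = Zv)
  for (b in names(params$planes)) {
    pl <- params$planes[[b]]
    mu <- pl$slope_g * pmin(Gv - pl$g0, 0) + pl$slope_z * pmin(Zv - pl$z0, 0)
    Fm[[paste0("M2_", b)]] <- -mu^2 / (2 * pl$sigma^2)
    Fm[[paste0("M1_", b)]] <- mu / pl$sigma^2
  }
  Fmat <- do.call(cbind, Fm)
  list(axes = ax, Fmat = Fmat, biomarkers = names(params$planes),
       wfull = as.vector(outer(trap_weights(ax$g), trap_weights(ax$z))))
}

target_weights <- function(surf, targets) {
  ws <- vapply(seq_len(nrow(targets)), function(i) {
    as.vector(outer(trap_weights_to(surf$axes$g, targets$ga_cutoff[i]),
                    trap_weights_to(surf$axes$z, percentile_to_z(targets$p[i]))))
  }, numeric(length(surf$wfull)))
  colnames(ws) <- targets$name
  ws
}

#' Screen a cohort
#'
#' Vectorized equivalent of [screen_record()] applied row-wise: identical
#' posterior mathematics, evaluated for many records at once.
#'
#' @param cohort data.frame with maternal covariates and optional raw
#'   biomarker columns `utapi`, `pappa`, `plgf` (NA = not measured).
#' @inheritParams screen_record
#' @param chunk internal batch size.
#' @return data.frame of risks, one column per target (named `risk_<name>`),
#'   plus `biomarkers_used`.
#' @export
screen_cohort <- function(cohort, params, targets = sga_targets(),
                          use_biomarkers = c("utapi", "pappa", "plgf"),
                          chunk = 32L) {
  stopifnot(inherits(params, "crp_params"))
  n <- nrow(cohort)
  surf <- engine_surfaces(params)
  W <- cbind(target_weights(surf, targets), full = surf$wfull)
  sh <- maternal_shift(cohort, params)
  mg <- params$mean_g + sh$dg
  mz <- params$mean_z + sh$dz
  q <- -0.5 / (1 - params$rho^2)
  a_g <- -2 * q * mg / params$sd_g^2 + 2 * q * params$rho * mz / (params$sd_g * params$sd_z)
  a_z <- -2 * q * mz / params$sd_z^2 + 2 * q * params$rho * mg / (params$sd_g * params$sd_z)

  # per-record column coefficients for the surface matrix
  bio <- surf$biomarkers
  Cmat <- matrix(0, nrow = 3 + 2 * length(bio), ncol = n)
  Cmat[1, ] <- 1; Cmat[2, ] <- a_g; Cmat[3, ] <- a_z
  used <- rep("", n)
  for (k in seq_along(bio)) {
    b <- bio[k]
    if (b %in% use_biomarkers && b %in% names(cohort)) {
      avail <- !is.na(cohort[[b]])
      if (any(avail)) {
        v <- rep(NA_real_, n)
        v[avail] <- log10(to_mom(cohort[[b]][avail], cohort[avail, , drop = FALSE],
                                 params$mom_regressions[[b]]))
        Cmat[2 + 2 * k, avail] <- 1                 # M2 coefficient
        Cmat[3 + 2 * k, avail] <- v[avail]          # M1 coefficient
        used[avail] <- paste0(used[avail], ifelse(nchar(used[avail]), "+", ""), b)
      }
    }
  }
  risks <- matrix(NA_real_, n, nrow(targets))
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    # direct exponentiation: the unnormalized log posterior is bounded far
    # inside double range for any plausible record; degenerate records fall
    # back to the per-record path with max-subtraction
    D <- exp(surf$Fmat %*% Cmat[, idx, drop = FALSE])
    m <- crossprod(W, D)                            # (targets+1) x |idx|
    den <- m[nrow(targets) + 1L, ]
    risks[idx, ] <- t(m[seq_len(nrow(targets)), , drop = FALSE] /
                        rep(den, each = nrow(targets)))
    bad <- idx[!is.finite(den) | den <= 0]
    for (k in bad) {
      risks[k, ] <- screen_record(cohort[k, , drop = FALSE], params, targets,
                                  use_biomarkers)
    }
  }
  out <- as.data.frame(risks)
  names(out) <- paste0("risk_", targets$name)
  out$biomarkers_used <- ifelse(nchar(used), used, "none")
  out
}
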