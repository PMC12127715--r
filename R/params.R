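#' Competing-risks model parameters
#'
#' Bundles everything the risk engine needs: the prior joint Gaussian of
#' (gestational age at delivery `g`, birth-weight Z-score `z`) -- baseline
#' means, SDs, correlation and additive maternal-factor effects on both means
#' -- one folded-plane likelihood and one MoM regression per biomarker, and the
#' integration grid.
#'
#' @param mean_g,mean_z baseline prior means of `g` (weeks) and `z`.
#' @param sd_g,sd_z prior SDs (> 0).
#' @param rho prior correlation, `|rho| < 1`.
#' @param effects_g,effects_z named numeric vectors of additive shifts of the
#'   prior means per maternal-factor indicator (see [profile_indicators()]).
#'   Either may be empty.
#' @param planes named list of [likelihood_plane()] objects (`utapi`, `pappa`,
#'   `plgf`).
#' @param mom_regressions named list of [mom_regression()] objects, same names.
#' @param grid list with `g_range`, `z_range`, `g_step`, `z_step`.
#' @return object of class `crp_params`.
#' @export
crp_params <- function(mean_g, mean_z, sd_g, sd_z, rho,
                       effects_g = numeric(), effects_z = numeric(),
                       planes = .default_planes(),
                       mom_regressions = .default_mom_regressions(),
                       grid = default_grid()) {
  stopifnot(sd_g > 0, sd_z > 0, abs(rho) < 1)
  if (length(effects_g)) stopifnot(!is.null(names(effects_g)))
  if (length(effects_z)) stopifnot(!is.null(names(effects_z)))
  stopifnot(all(vapply(planes, inherits, TRUE, "likelihood_plane")),
            all(vapply(mom_regressions, inherits, TRUE, "mom_regression")))
  structure(list(mean_g = mean_g, mean_z = mean_z, sd_g = sd_g, sd_z = sd_z,
                 rho = rho, effects_g = effects_g, effects_z = effects_z,
                 planes = planes, mom_regressions = mom_regressions,
                 grid = grid),
            class = "crp_params")
}

#' Default integration grid
#'
#' @param g_step,z_step grid steps in weeks and Z units.
#' @return grid specification list.
#' @export
default_grid <- function(g_step = 0.05, z_step = 0.02) {
  list(g_range = c(24, 43), z_range = c(-5, 5), g_step = g_step, z_step = z_step)
}

#' Default (calibrated) competing-risks parameters
#'
#' The shipped defaults: the prior baseline and maternal effect maps are the
#' output of [calibrate_generator()] run against the reference cohort's
#' outcome incidences, and the biomarker models are the package's documented
#' synthetic stand-ins.
#'
#' @param grid optional grid override.
#' @return a [crp_params()] object.
#' @export
default_params <- function(grid = default_grid()) {
  s <- .calibrated_solution
  eff_g <- s$lam_g * .effect_shape_g
  eff_z <- s$lam_z * .effect_shape_z + s$kappa * eff_g
  crp_params(mean_g = s$mean_g, mean_z = s$mean_z, sd_g = s$sd_g,
             sd_z = s$sd_z, rho = s$rho,
             effects_g = eff_g, effects_z = eff_z, grid = grid)
}

#' Maternal-factor indicator matrix
#'
#' Expands maternal profiles into the 0/1 indicators named by the effect maps:
#' `nulliparous`, `smoker`, `chronic_htn`, `diabetes`, `sle_aps`,
#' `conception_oi`, `conception_ivf`, `prev_pe`, `prev_sga`,
#' `prev_stillbirth`. History indicators are zero for nulliparous women.
#'
#' @param profiles data.frame of maternal profiles (see [sample_maternal()]).
#' @return numeric matrix, one row per profile.
#' @export
profile_indicators <- function(profiles) {
  need <- c("parity", "smoker", "chronic_htn", "diabetes", "sle_aps", "conception")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    stop("maternal profiles are missing required columns: ", paste(miss, collapse = ", "))
  }
  parous <- profiles$parity == "parous"
  hist0 <- function(col) {
    v <- if (col %in% names(profiles)) as.numeric(profiles[[col]]) else 0
    v <- ifelse(is.na(v), 0, v)
    v * as.numeric(parous)
  }
  cbind(
    nulliparous = as.numeric(!parous),
    smoker = as.numeric(profiles$smoker),
    chronic_htn = as.numeric(profiles$chronic_htn),
    diabetes = as.numeric(profiles$diabetes),
    sle_aps = as.numeric(profiles$sle_aps),
    conception_oi = as.numeric(profiles$conception == "ovulation_induction"),
    conception_ivf = as.numeric(profiles$conception == "ivf"),
    prev_pe = hist0("prev_pe"),
    prev_sga = hist0("prev_sga"),
    prev_stillbirth = hist0("prev_stillbirth")
  )
}

#' Prior mean shifts for maternal profiles
#'
#' @param profiles data.frame of maternal profiles.
#' @param params a [crp_params()].
#' @return data.frame with columns `dg` and `dz`, one row per profile.
#' @export
maternal_shift <- function(profiles, params) {
  ind <- profile_indicators(profiles)
  pick <- function(effects) {
    if (!length(effects)) return(rep(0, nrow(ind)))
    unknown <- setdiff(names(effects), colnames(ind))
    if (length(unknown)) stop("unknown effect-map terms: ", paste(unknown, collapse = ", "))
    drop(ind[, names(effects), drop = FALSE] %*% effects)
  }
  data.frame(dg = pick(params$effects_g), dz = pick(params$effects_z))
}

#' @export
print.crp_params <- function(x, ...) {
  cat("Competing-risks model parameters\n")
  cat(sprintf("  prior: g ~ N(%.3f%+.3f shifts, %.3f), z ~ N(%.3f%+.3f shifts, %.3f), rho = %.3f\n",
              x$mean_g, 0, x$sd_g, x$mean_z, 0, x$sd_z, x$rho))
  cat("  biomarkers:", paste(names(x$planes), collapse = ", "), "\n")
  cat(sprintf("  grid: g [%g, %g] step %g; z [%g, %g] step %g\n",
              x$grid$g_range[1], x$grid$g_range[2], x$grid$g_step,
              x$grid$z_range[1], x$grid$z_range[2], x$grid$z_step))
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON parameter files

.params_blocks <- c("prior", "likelihood_planes", "mom_regressions", "grid", "chart")

#' Write competing-risks parameters to a JSON file
#'
#' @param params a [crp_params()].
#' @param path output file.
#' @param chart optional [weight_chart()] stored alongside.
#' @export
write_params <- function(params, path, chart = default_weight_chart()) {
  obj <- list(
    prior = list(mean_g = params$mean_g, mean_z = params$mean_z,
                 sd_g = params$sd_g, sd_z = params$sd_z, rho = params$rho,
                 effects_g = as.list(params$effects_g),
                 effects_z = as.list(params$effects_z)),
    likelihood_planes = lapply(params$planes, unclass),
    mom_regressions = lapply(params$mom_regressions, unclass),
    grid = params$grid,
    chart = unclass(chart)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load competing-risks parameters from a JSON file
#'
#' The schema is validated: the blocks `prior`, `likelihood_planes` and
#' `mom_regressions` are required, unknown top-level blocks are rejected, and
#' all numeric invariants are re-checked on construction.
#'
#' @param path JSON file written by [write_params()] (or hand-edited in the
#'   same schema).
#' @return list with elements `params` (a [crp_params()]) and `chart`
#'   (a [weight_chart()] or `NULL`).
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), .params_blocks)
  if (length(unknown)) {
    stop("unknown blocks in parameter file: ", paste(unknown, collapse = ", "))
  }
  need <- c("prior", "likelihood_planes", "mom_regressions")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("parameter file is missing blocks: ", paste(miss, collapse = ", "))
  pr <- obj$prior
  planes <- lapply(obj$likelihood_planes, function(p) {
    likelihood_plane(p$biomarker, p$slope_g, p$slope_z, p$sigma, p$g0, p$z0)
  })
  regs <- lapply(obj$mom_regressions, function(r) {
    terms <- r$terms
    if (is.data.frame(terms)) {
      terms <- lapply(seq_len(nrow(terms)), function(i) {
        tm <- as.list(terms[i, ])
        tm[!vapply(tm, function(v) is.null(v) || (length(v) == 1 && is.na(v)), TRUE)]
      })
    }
    mom_regression(r$biomarker, r$reference_log10, terms)
  })
  grid <- if (!is.null(obj$grid)) {
    list(g_range = as.numeric(obj$grid$g_range), z_range = as.numeric(obj$grid$z_range),
         g_step = obj$grid$g_step, z_step = obj$grid$z_step)
  } else default_grid()
  params <- crp_params(pr$mean_g, pr$mean_z, pr$sd_g, pr$sd_z, pr$rho,
                       effects_g = unlist(pr$effects_g) %||% numeric(),
                       effects_z = unlist(pr$effects_z) %||% numeric(),
                       planes = planes, mom_regressions = regs, grid = grid)
  chart <- if (!is.null(obj$chart)) {
    weight_chart(obj$chart$mean_coef, obj$chart$sd_coef, obj$chart$ga_support)
  }
  list(params = params, chart = chart)
}
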