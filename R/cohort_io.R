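#' Cohort tables: reading, validation, writing
#'
#' Cohort CSVs are comma-separated UTF-8 with '.' decimals; empty cells are
#' missing values; gestational ages are decimal weeks (37 weeks + 3 days is
#' 37.4286). Reading validates the schema, coerces types with row-level error
#' reporting, and applies the study inclusion rules: screening between 11+0
#' and 13+6 weeks, delivery (when outcome columns are present) at or after
#' 24+0 weeks. Rows failing inclusion are returned in a side table with
#' reasons rather than silently dropped.
#'
#' @name cohort_io
NULL

.maternal_required <- c("age", "weight", "height", "race", "smoker",
                        "conception", "chronic_htn", "diabetes", "sle_aps",
                        "parity", "ga_at_screen")
.maternal_optional <- c("id", "prev_pe", "prev_sga", "prev_stillbirth",
                        "interpregnancy_interval", "ga_last_delivery")
.biomarker_cols <- c("utapi", "pappa", "plgf", "map_mom")
.outcome_cols <- c("ga_delivery", "birth_weight", "bw_z", "sga10", "sga3", "pe")

.numeric_cols <- c("age", "weight", "height", "ga_at_screen",
                   "interpregnancy_interval", "ga_last_delivery",
                   .biomarker_cols, "ga_delivery", "birth_weight", "bw_z")
.logical_cols <- c("smoker", "chronic_htn", "diabetes", "sle_aps",
                   "prev_pe", "prev_sga", "prev_stillbirth",
                   "sga10", "sga3", "pe")

ga_screen_window <- c(11.0, 13 + 6 / 7)

#' Read and validate a cohort CSV
#'
#' @param path CSV file.
#' @return list with `cohort` (the validated rows), `excluded` (rows failing
#'   inclusion rules, with a `reason` column).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  miss <- setdiff(.maternal_required, names(raw))
  if (length(miss)) stop("cohort file is missing required columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(names(raw), c(.maternal_required, .maternal_optional,
                                   .biomarker_cols, .outcome_cols))
  if (length(unknown)) {
    warning("ignoring unknown cohort columns: ", paste(unknown, collapse = ", "))
  }
  df <- raw
  errs <- character(0)
  for (col in intersect(.numeric_cols, names(df))) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      errs <- c(errs, sprintf("column '%s': malformed number at line %s",
                              col, paste(bad + 1L, collapse = ", ")))
    }
    df[[col]] <- num
  }
  for (col in intersect(.logical_cols, names(df))) {
    v <- toupper(trimws(df[[col]]))
    lg <- ifelse(is.na(v), NA, v %in% c("TRUE", "T", "1", "YES"))
    bad <- which(!is.na(v) & !v %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
    if (length(bad)) {
      errs <- c(errs, sprintf("column '%s': malformed logical at line %s",
                              col, paste(bad + 1L, collapse = ", ")))
    }
    df[[col]] <- lg
  }
  if (length(errs)) stop("cohort file has malformed values:\n  ", paste(errs, collapse = "\n  "))
  has_bw <- "birth_weight" %in% names(df)
  has_ga <- "ga_delivery" %in% names(df)
  if (has_bw != has_ga) {
    stop("birth_weight and ga_delivery must be jointly present or jointly absent")
  }
  if (has_bw && any(xor(is.na(df$birth_weight), is.na(df$ga_delivery)))) {
    stop("birth weight and GA at delivery must be jointly present or jointly absent per row")
  }
  reason <- rep(NA_character_, nrow(df))
  out_win <- !is.na(df$ga_at_screen) &
    (df$ga_at_screen < ga_screen_window[1] | df$ga_at_screen > ga_screen_window[2])
  reason[out_win] <- "screening GA outside 11+0 to 13+6 weeks"
  if (has_ga) {
    early <- !is.na(df$ga_delivery) & df$ga_delivery < 24
    reason[early & is.na(reason)] <- "delivery before 24+0 weeks"
  }
  keep <- is.na(reason)
  excluded <- df[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  list(cohort = df[keep, , drop = FALSE], excluded = excluded)
}

#' Write a cohort CSV
#'
#' Numeric columns are serialized with 10 significant digits so that repeated
#' runs can be compared byte-for-byte.
#'
#' @param cohort data.frame.
#' @param path output CSV.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.10g", out[[col]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Outcome label sets for evaluation
#'
#' Builds the outcome definitions evaluated in validation studies: SGA below
#' the 10th/3rd percentile delivered before 37/32 weeks, each in two variants
#' -- all SGA, and SGA without pre-eclampsia (PE cases that are SGA are removed
#' from the evaluation subset entirely: cases are SGA and not PE, controls are
#' non-SGA; records NA-ed out are skipped by the evaluators).
#'
#' @param cohort cohort with `sga10`, `sga3`, `ga_delivery`, `pe` columns.
#' @return named list of logical vectors (with NA marking dropped records).
#' @export
outcome_labels <- function(cohort) {
  defs <- expand.grid(p = c("sga10", "sga3"), cut = c(37, 32))
  out <- list()
  for (i in seq_len(nrow(defs))) {
    sga <- cohort[[as.character(defs$p[i])]]
    lab <- sga & cohort$ga_delivery < defs$cut[i]
    nm <- sprintf("%s_pre%d", defs$p[i], defs$cut[i])
    out[[nm]] <- lab
    no_pe <- lab
    no_pe[lab & cohort$pe] <- NA
    out[[paste0(nm, "_noPE")]] <- no_pe
  }
  out
}

#' Nested biomarker combinations reported in validation studies
#'
#' @return named list of biomarker subsets.
#' @export
biomarker_combinations <- function() {
  list(
    mf = character(0),
    mf_utapi = "utapi",
    mf_utapi_pappa = c("utapi", "pappa"),
    mf_utapi_plgf = c("utapi", "plgf"),
    mf_plgf_pappa = c("plgf", "pappa"),
    mf_utapi_pappa_plgf = c("utapi", "pappa", "plgf")
  )
}

#' Load a generator configuration from YAML
#'
#' Any field omitted from the file keeps its package default (the calibrated
#' reference-cohort conditions).
#'
#' @param path YAML file with optional fields `n`, `seed`, `missingness`
#'   (`utapi`, `plgf`), `pe_targets`.
#' @return a [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(y)[names(y) == "FALSE"] <- "n"
  known <- c("n", "seed", "missingness", "pe_targets")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown generator config fields: ", paste(unknown, collapse = ", "))
  miss <- .default_missingness
  if (!is.null(y$missingness)) miss[names(y$missingness)] <- unlist(y$missingness)
  pe <- .default_pe_targets
  if (!is.null(y$pe_targets)) pe[names(y$pe_targets)] <- y$pe_targets
  generator_config(n = y$n %||% 35170, seed = y$seed %||% 1,
                   missingness = miss, pe_targets = pe)
}

#' Run the full pipeline on one synthetic cohort
#'
#' simulate -> screen (all biomarker combinations) -> evaluate discrimination
#' for every outcome definition -> calibration for the before-37-weeks targets
#' -> comparator models and McNemar comparison, all under one master seed.
#'
#' @param config a [generator_config()].
#' @param comparators named list of [logistic_model()] objects, or `NULL` to
#'   load the shipped synthetic stubs.
#' @param fpr fixed false-positive rate for detection rates and McNemar.
#' @return list with `cohort`, `risks` (per combination), `performance`,
#'   `calibration`, `comparison`, and a `manifest` of run metadata.
#' @export
run_end_to_end <- function(config = generator_config(n = 5000), comparators = NULL,
                           fpr = 0.10) {
  if (config$n < 1) stop("config error: cohort size must be at least 1")
  cohort <- simulate_cohort(config)
  combos <- biomarker_combinations()
  targets <- sga_targets()
  risks <- lapply(combos, function(bio) {
    screen_cohort(cohort, config$params, targets, use_biomarkers = bio)
  })
  labels <- outcome_labels(cohort)
  # discrimination: evaluate each combination's matching risk column
  perf <- list()
  for (cmb in names(combos)) {
    rt <- risks[[cmb]]
    for (i in seq_len(nrow(targets))) {
      base <- sprintf("%s_pre%d", ifelse(targets$p[i] == 0.10, "sga10", "sga3"),
                      targets$ga_cutoff[i])
      for (variant in c(base, paste0(base, "_noPE"))) {
        lab <- labels[[variant]]
        keep <- !is.na(lab)
        row <- if (any(lab[keep]) && !all(lab[keep])) {
          ev <- detection_rate_at_fpr(rt[[paste0("risk_", targets$name[i])]][keep],
                                      lab[keep], fpr)
          au <- roc_auc(rt[[paste0("risk_", targets$name[i])]][keep], lab[keep])
          data.frame(method = cmb, outcome = variant, n_cases = ev$n_cases,
                     auc = au$auc, auc_lo = au$auc_ci[1], auc_hi = au$auc_ci[2],
                     dr = ev$dr, dr_lo = ev$dr_ci[1], dr_hi = ev$dr_ci[2])
        } else {
          # a cohort too small to carry cases of this outcome definition
          data.frame(method = cmb, outcome = variant, n_cases = sum(lab[keep]),
                     auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                     dr = NA_real_, dr_lo = NA_real_, dr_hi = NA_real_)
        }
        perf[[length(perf) + 1L]] <- row
      }
    }
  }
  perf <- do.call(rbind, c(perf, make.row.names = FALSE))
  # calibration for the before-37-weeks targets
  cal <- list()
  for (cmb in names(combos)) {
    for (tn in c("p10_ga37", "p3_ga37")) {
      lab <- labels[[sprintf("%s_pre37", ifelse(tn == "p10_ga37", "sga10", "sga3"))]]
      cf <- tryCatch(calibration_fit(risks[[cmb]][[paste0("risk_", tn)]], lab),
                     error = function(e) list(slope = NA_real_, intercept = NA_real_,
                                              slope_ci = c(NA_real_, NA_real_),
                                              intercept_ci = c(NA_real_, NA_real_)))
      cal[[length(cal) + 1L]] <- data.frame(
        method = cmb, target = tn, slope = cf$slope,
        slope_lo = cf$slope_ci[1], slope_hi = cf$slope_ci[2],
        intercept = cf$intercept,
        intercept_lo = cf$intercept_ci[1], intercept_hi = cf$intercept_ci[2]
      )
    }
  }
  cal <- do.call(rbind, c(cal, make.row.names = FALSE))
  # comparators on the UtA-PI subset, against the full competing-risks model
  if (is.null(comparators)) {
    comparators <- read_comparators(system.file("extdata", "comparators.json",
                                                package = "sgascreen"))
  }
  feats <- comparator_features(cohort, config$params)
  cr_risk <- risks$mf_utapi_pappa_plgf$risk_p10_ga37
  lab <- labels$sga10_pre37
  comparison <- list()
  for (cm in comparators) {
    absent <- setdiff(names(cm$terms), names(feats))
    if (length(absent)) {
      comparison[[cm$name]] <- list(skipped = paste("missing feature(s):",
                                                    paste(absent, collapse = ", ")))
      next
    }
    have <- stats::complete.cases(feats[, names(cm$terms), drop = FALSE])
    keep <- have & !is.na(lab)
    cmp_risk <- logistic_risk(feats[keep, , drop = FALSE], cm)
    mc <- mcnemar_fixed_fpr(cr_risk[keep], cmp_risk, lab[keep], fpr)
    ev_cr <- detection_rate_at_fpr(cr_risk[keep], lab[keep], fpr)
    ev_cmp <- detection_rate_at_fpr(cmp_risk, lab[keep], fpr)
    comparison[[cm$name]] <- list(
      n = sum(keep), dr_competing_risks = ev_cr$dr, dr_comparator = ev_cmp$dr,
      discordant = mc$discordant, p_value = mc$p_value, method = mc$method
    )
  }
  manifest <- list(
    n = config$n, seed = config$seed, fpr = fpr,
    params_hash = digest_params(config$params),
    timestamp = NULL  # deliberately omitted: reports must be byte-identical across runs
  )
  list(cohort = cohort, risks = risks, performance = perf, calibration = cal,
       comparison = comparison, manifest = manifest)
}

digest_params <- function(params) {
  # cheap stable hash: sum of a few invariant transforms of the numeric content
  v <- unlist(list(params$mean_g, params$mean_z, params$sd_g, params$sd_z,
                   params$rho, params$effects_g, params$effects_z,
                   lapply(params$planes, function(p) c(p$slope_g, p$slope_z, p$sigma))))
  sprintf("%.0f", sum(abs(v) * seq_along(v)) * 1e6)
}

#' Write an end-to-end report to JSON
#'
#' @param report output of [run_end_to_end()].
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  obj <- report[c("performance", "calibration", "comparison", "manifest")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
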