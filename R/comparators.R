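#' Logistic-regression comparator models
#'
#' Published first-trimester SGA prediction models are typically logistic
#' regressions on maternal factors and biomarker log10 MoMs (UtA-PI, PAPP-A,
#' sometimes mean arterial pressure). This module evaluates any such equation
#' so it can be compared head-to-head with the competing-risks model at a
#' fixed false-positive rate. Coefficients are loaded from an editable JSON
#' file; the file shipped with the package contains synthetic placeholder
#' equations (clearly labelled), not transcriptions of published coefficients.
#'
#' @name comparators
NULL

#' Construct a logistic comparator model
#'
#' @param name model identifier.
#' @param intercept intercept on the log-odds scale.
#' @param terms named list mapping feature names to coefficients. Feature
#'   names refer to columns of the feature table passed to [logistic_risk()]
#'   (maternal covariates or `log10mom_<biomarker>` columns).
#' @return object of class `logistic_model`.
#' @export
logistic_model <- function(name, intercept, terms) {
  stopifnot(is.character(name), is.numeric(intercept), length(intercept) == 1)
  co <- unlist(terms)
  stopifnot(is.numeric(co), !is.null(names(co)))
  structure(list(name = name, intercept = intercept, terms = co),
            class = "logistic_model")
}

#' Individual risk from a logistic comparator
#'
#' Inverse-logit of `intercept + sum(coefficient * feature)`.
#'
#' @param features data.frame (or one-row list) carrying every feature the
#'   model names; extra columns are ignored.
#' @param model a [logistic_model()].
#' @return probabilities in (0, 1).
#' @export
logistic_risk <- function(features, model) {
  stopifnot(inherits(model, "logistic_model"))
  miss <- setdiff(names(model$terms), names(features))
  if (length(miss)) {
    stop(sprintf("comparator '%s' needs missing feature(s): %s",
                 model$name, paste(miss, collapse = ", ")))
  }
  eta <- rep(model$intercept, max(1L, nrow(features)))
  for (f in names(model$terms)) {
    x <- as.numeric(features[[f]])
    if (anyNA(x)) stop(sprintf("comparator '%s' feature '%s' has missing values", model$name, f))
    eta <- eta + model$terms[[f]] * x
  }
  inv_logit(eta)
}

#' Load comparator models from a JSON file
#'
#' @param path JSON file: an array of objects with `name`, `intercept` and a
#'   `terms` object of feature-coefficient pairs.
#' @return named list of [logistic_model()] objects.
#' @export
read_comparators <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(obj, function(m) logistic_model(m$name, m$intercept, m$terms))
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Comparator feature table for a cohort
#'
#' Builds the feature columns comparator equations use: maternal covariates
#' (centered age, weight, height, indicator columns) and `log10mom_<b>`
#' columns for each measured biomarker.
#'
#' @param cohort cohort data.frame with raw biomarker columns.
#' @param params a [crp_params()] supplying the MoM regressions.
#' @return data.frame of features.
#' @export
comparator_features <- function(cohort, params) {
  ind <- as.data.frame(profile_indicators(cohort))
  out <- cbind(
    data.frame(age_c = cohort$age - 32, weight_c = cohort$weight - 69,
               height_c = cohort$height - 164),
    ind
  )
  for (b in names(params$mom_regressions)) {
    col <- rep(NA_real_, nrow(cohort))
    if (b %in% names(cohort)) {
      avail <- !is.na(cohort[[b]])
      col[avail] <- log10(to_mom(cohort[[b]][avail], cohort[avail, , drop = FALSE],
                                 params$mom_regressions[[b]]))
    }
    out[[paste0("log10mom_", b)]] <- col
  }
  if ("map_mom" %in% names(cohort)) out$log10mom_map <- log10(cohort$map_mom)
  out
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic comparator '%s': logit(p) = %.3f + %s\n", x$name, x$intercept,
              paste(sprintf("%+.3f*%s", x$terms, names(x$terms)), collapse = " ")))
  invisible(x)
}
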