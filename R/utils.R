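# Internal numerical helpers.

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) 1 / (1 + exp(-x))

#' @noRd
gauss_legendre <- function(n) {
  # Golub-Welsch: nodes/weights on [-1, 1]
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

.gl24 <- NULL

gl_nodes <- function() {
  if (is.null(.gl24)) {
    # cache in the package namespace on first use
    utils::assignInMyNamespace(".gl24", gauss_legendre(24))
  }
  .gl24
}

#' Bivariate standard-normal rectangle probability
#'
#' `P(X < a, Y < h)` for standard bivariate normal with correlation `rho`,
#' computed by Gauss-Legendre quadrature of `phi(u) * Phi((a - rho u)/sqrt(1-rho^2))`
#' over `u < h`. Vectorized over `a` and `h` (recycled to common length);
#' `rho` is scalar.
#'
#' @param a,h upper limits on the two coordinates (standardized scale).
#' @param rho correlation, `|rho| < 1`.
#' @return vector of probabilities.
#' @keywords internal
pbvn <- function(a, h, rho) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  n <- max(length(a), length(h))
  a <- rep_len(a, n)
  h <- rep_len(h, n)
  gl <- gl_nodes()
  lo <- -8.5
  m <- pmax(h, lo)
  half <- (m - lo) / 2
  mid <- (m + lo) / 2
  U <- outer(half, gl$x) + mid
  s <- sqrt(1 - rho^2)
  drop((stats::dnorm(U) * stats::pnorm((a - rho * U) / s)) %*% gl$w) * half
}

#' Wilson score confidence interval for a proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @keywords internal
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Derive named per-stage random seeds from one master seed
#'
#' One global seed is expanded into reproducible sub-seeds so that the
#' maternal, outcome, biomarker and label sampling stages can be re-run
#' independently.
#'
#' @param seed master seed (integer).
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, all below `2^31`.
#' @export
seed_streams <- function(seed, stages = c("maternal", "outcome", "biomarker",
                                          "pe", "missingness")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
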