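#' Covariate process specifications
#'
#' Constructors for the stationary covariate processes used throughout the
#' simulation designs: i.i.d. standard normal draws, a zero-initialized AR(1)
#' recursion with standard normal innovations, a period-12 sinusoid with
#' Gaussian noise, and i.i.d. uniform draws.
#'
#' @param sd Innovation / noise standard deviation.
#' @param coef AR(1) coefficient in (-1, 1).
#' @param period Sinusoid period (time points per cycle).
#' @param min,max Uniform bounds.
#' @return A `cov_spec` object usable in [gen_covariates()] and
#'   [simulate_tvmt()].
#' @examples
#' gen_covariates(cov_ar1(-0.5), 5)
#' @export
cov_iid_normal <- function(sd = 1) {
  new_cov_spec("iid_normal", sd = sd)
}

#' @rdname cov_iid_normal
#' @export
cov_ar1 <- function(coef = 0.5, sd = 1) {
  if (abs(coef) >= 1) abort("AR(1) coefficient must lie in (-1, 1).")
  new_cov_spec("ar1", coef = coef, sd = sd)
}

#' @rdname cov_iid_normal
#' @export
cov_seasonal <- function(period = 12, sd = 0.5) {
  if (period <= 0) abort("`period` must be positive.")
  new_cov_spec("seasonal", period = period, sd = sd)
}

#' @rdname cov_iid_normal
#' @export
cov_iid_unif <- function(min = -10, max = 1) {
  if (min >= max) abort("`min` must be below `max`.")
  new_cov_spec("iid_uniform", min = min, max = max)
}

new_cov_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "cov_spec")
}

#' Generate a covariate column
#'
#' Draws `n` values of the covariate process described by a
#' [cov_spec][cov_iid_normal] object, using the session RNG.
#'
#' @param spec A `cov_spec`.
#' @param n Number of time points.
#' @return Numeric vector of length `n`.
#' @export
gen_covariates <- function(spec, n) {
  if (!inherits(spec, "cov_spec")) abort("`spec` must be a cov_spec.")
  if (n < 1) abort("`n` must be at least 1.")
  switch(spec$kind,
    iid_normal = rnorm(n, sd = spec$sd),
    ar1 = {
      eps <- rnorm(n, sd = spec$sd)
      z <- numeric(n)
      z[1] <- eps[1]            # Z_0 = 0, so Z_1 is pure innovation
      for (t in seq_len(n)[-1]) z[t] <- spec$coef * z[t - 1] + eps[t]
      z
    },
    seasonal = sin(2 * pi * seq_len(n) / spec$period) +
      rnorm(n, sd = spec$sd),
    iid_uniform = runif(n, spec$min, spec$max),
    abort(sprintf("unknown covariate kind '%s'.", spec$kind))
  )
}

#' Simulate a TVMTTINAR(1) series
#'
#' Iterates the mixture-thinning threshold recursion with Poisson
#' innovations, discarding a burn-in so the returned stretch is effectively
#' stationary. Covariates are either generated from `cov_spec` objects (one
#' per explanatory variable) for the full `n + burn_in` horizon, or supplied
#' as a numeric matrix with at least `n + burn_in` rows (which lets the
#' covariate path be held fixed across replications).
#'
#' @param model A [tvmt_model()].
#' @param n Number of observations to return.
#' @param covariates List of [cov_spec][cov_iid_normal] objects of length
#'   `q`, or a numeric matrix (without intercept) with `>= n + burn_in` rows.
#'   Omit (NULL) when `q = 0`.
#' @param burn_in Number of initial steps discarded (default 500).
#' @param x0 Initial count; default a Poisson(\eqn{\lambda}) draw.
#' @return A tibble with columns `t`, `x`, and `z1..zq`, `n` rows.
#' @examples
#' m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
#' set.seed(1)
#' head(simulate_tvmt(m, 10, covariates = list(cov_iid_normal())))
#' @export
simulate_tvmt <- function(model, n, covariates = NULL, burn_in = 500,
                          x0 = NULL) {
  stopifnot(inherits(model, "tvmt_model"))
  Z <- resolve_covariates(covariates, model$q, n, burn_in)
  n_tot <- n + burn_in
  phi1 <- plogis(drop(Z %*% model$beta1))
  phi2 <- plogis(drop(Z %*% model$beta2))
  x <- integer(n_tot)
  prev <- if (is.null(x0)) rpois(1, model$lambda) else as.integer(x0)
  for (t in seq_len(n_tot)) {
    i1 <- regime_indicator(prev, model$r, model$R)
    surv <- if (i1) thin_binom_sample(prev, phi1[t])
            else thin_nbinom_sample(prev, phi2[t])
    x[t] <- surv + rpois(1, model$lambda)
    prev <- x[t]
  }
  keep <- seq.int(burn_in + 1L, n_tot)
  out <- tibble(t = seq_len(n), x = x[keep])
  if (model$q > 0) {
    zobs <- Z[keep, -1, drop = FALSE]
    colnames(zobs) <- paste0("z", seq_len(model$q))
    out <- dplyr::bind_cols(out, as_tibble(zobs))
  }
  out
}

#' Simulate an MTTINAR(1) series
#'
#' Constant-coefficient counterpart of [simulate_tvmt()]: no covariates,
#' thinning parameters `alpha1`/`alpha2`.
#'
#' @param model An [mtt_model()].
#' @inheritParams simulate_tvmt
#' @return A tibble with columns `t` and `x`.
#' @export
simulate_mtt <- function(model, n, burn_in = 500, x0 = NULL) {
  stopifnot(inherits(model, "mtt_model"))
  n_tot <- n + burn_in
  x <- integer(n_tot)
  prev <- if (is.null(x0)) rpois(1, model$lambda) else as.integer(x0)
  for (t in seq_len(n_tot)) {
    i1 <- regime_indicator(prev, model$r, model$R)
    surv <- if (i1) thin_binom_sample(prev, model$alpha1)
            else thin_nbinom_sample(prev, model$alpha2)
    x[t] <- surv + rpois(1, model$lambda)
    prev <- x[t]
  }
  tibble(t = seq_len(n), x = x[seq.int(burn_in + 1L, n_tot)])
}

#' Simulate a single-regime time-varying INAR(1) series
#'
#' The no-threshold processes used as null designs for the piecewise-
#' structure test: one thinning operator throughout, with a logistic-link
#' time-varying coefficient.
#'
#' @param beta Coefficient vector (intercept first).
#' @param lambda Poisson innovation mean.
#' @param operator `"binomial"` or `"nbinom"` thinning.
#' @inheritParams simulate_tvmt
#' @return A tibble with columns `t`, `x`, `z1..zq`.
#' @export
simulate_tvinar <- function(beta, lambda, n, covariates,
                            operator = c("binomial", "nbinom"),
                            burn_in = 500, x0 = NULL) {
  operator <- match.arg(operator)
  q <- length(beta) - 1L
  Z <- resolve_covariates(covariates, q, n, burn_in)
  n_tot <- n + burn_in
  phi <- plogis(drop(Z %*% beta))
  x <- integer(n_tot)
  prev <- if (is.null(x0)) rpois(1, lambda) else as.integer(x0)
  for (t in seq_len(n_tot)) {
    surv <- if (operator == "binomial") thin_binom_sample(prev, phi[t])
            else thin_nbinom_sample(prev, phi[t])
    x[t] <- surv + rpois(1, lambda)
    prev <- x[t]
  }
  keep <- seq.int(burn_in + 1L, n_tot)
  out <- tibble(t = seq_len(n), x = x[keep])
  if (q > 0) {
    zobs <- Z[keep, -1, drop = FALSE]
    colnames(zobs) <- paste0("z", seq_len(q))
    out <- dplyr::bind_cols(out, as_tibble(zobs))
  }
  out
}

# Build the full-horizon covariate matrix (with intercept) for simulation.
resolve_covariates <- function(covariates, q, n, burn_in) {
  n_tot <- n + burn_in
  if (q == 0) {
    if (!is.null(covariates)) abort("model has q = 0; drop `covariates`.")
    return(matrix(1, n_tot, 1))
  }
  if (is.null(covariates)) abort("`covariates` required when q > 0.")
  if (is.matrix(covariates)) {
    if (nrow(covariates) < n_tot) {
      abort(sprintf("covariate matrix has %d rows; need at least %d.",
                    nrow(covariates), n_tot))
    }
    if (ncol(covariates) != q) abort("covariate matrix must have q columns.")
    return(cbind(1, covariates[seq_len(n_tot), , drop = FALSE]))
  }
  if (!is.list(covariates) || length(covariates) != q) {
    abort("`covariates` must be a list of q cov_spec objects or a matrix.")
  }
  cbind(1, vapply(covariates, gen_covariates, numeric(n_tot), n = n_tot))
}
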