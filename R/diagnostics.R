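#' Pearson residuals of a fitted (or specified) model
#'
#' Standardized one-step prediction errors
#' \eqn{Pr_t = (X_t - \hat E[X_t \mid X_{t-1}, Z_t]) /
#'      \sqrt{\widehat{Var}(X_t \mid X_{t-1}, Z_t)}} over the transitions of
#' `data`. Under a correctly specified model they have mean near 0,
#' variance near 1 and negligible autocorrelation.
#'
#' @param data Series tibble.
#' @param object A `tvmt_fit` or [tvmt_model()].
#' @return Numeric vector of length `nrow(data) - 1`.
#' @export
pearson_residuals <- function(data, object) {
  model <- as_tvmt_model(object)
  sm <- series_matrices(data, model$q)
  cm <- cond_mean_series(sm$x, sm$Z, model$beta1, model$beta2,
                         model$lambda, model$r, model$R)
  v <- ifelse(cm$i1, cm$phi1 * (1 - cm$phi1),
              cm$phi2 * (1 + cm$phi2)) * cm$xp + model$lambda
  if (any(v <= 0)) abort("non-positive conditional variance encountered.")
  (cm$xt - cm$g) / sqrt(v)
}

#' @export
residuals.tvmt_fit <- function(object, data = object$data, ...) {
  if (is.null(data)) abort("fit carries no data; pass `data` explicitly.")
  pearson_residuals(data, object)
}

#' Root mean square one-step prediction error
#'
#' \eqn{RMS = \sqrt{(n-1)^{-1} \sum_{t=2}^{n}
#'      (X_t - \hat E[X_t \mid X_{t-1}, Z_t])^2}} — the square root of the
#' CLS criterion averaged over the transitions.
#'
#' @inheritParams pearson_residuals
#' @return Non-negative scalar.
#' @export
model_rms <- function(data, object) {
  model <- as_tvmt_model(object)
  sm <- series_matrices(data, model$q)
  if (length(sm$x) < 2) abort("need at least 2 observations.")
  cm <- cond_mean_series(sm$x, sm$Z, model$beta1, model$beta2,
                         model$lambda, model$r, model$R)
  sqrt(mean((cm$xt - cm$g)^2))
}

#' Information criteria
#'
#' Standard penalized log-likelihoods: `AIC = -2 logLik + 2k`,
#' `BIC = -2 logLik + k log(n)`, with `k = 2q + 3` for a TVMTTINAR(1) fit
#' with known threshold.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Effective sample size.
#' @return List with `aic` and `bic`.
#' @examples
#' info_criteria(-100, k = 3, n = 100)
#' @export
info_criteria <- function(loglik, k, n) {
  if (n < 1) abort("`n` must be at least 1.")
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

#' Proportion of transitions driven by the below-threshold branch
#'
#' Fraction of lagged counts \eqn{X_0, \dots, X_{n-1}} (the values that
#' decide the regime of the following step) at or below the threshold `r`.
#' Independent of `R` — it reports where the series sits relative to `r`.
#'
#' @param data Series tibble.
#' @param r Integer threshold.
#' @return Proportion in \[0, 1\].
#' @export
below_threshold_rate <- function(data, r) {
  x <- series_matrices(data)$x
  mean(x[-length(x)] <= r)
}

#' Goodness-of-fit summary for a fitted model
#'
#' Bundles the Pearson-residual mean and variance, the RMS one-step error,
#' AIC/BIC (CML fits), and the below-threshold rate into a one-row tibble.
#'
#' @param fit A `tvmt_fit`.
#' @param data Series tibble; defaults to the data stored in the fit.
#' @return One-row tibble.
#' @export
diagnose <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "tvmt_fit"))
  if (is.null(data)) abort("fit carries no data; pass `data` explicitly.")
  pr <- pearson_residuals(data, fit)
  k <- 2 * fit$q + 3
  ll <- if (fit$method == "CML") fit$objective else NA_real_
  ic <- if (is.na(ll)) list(aic = NA_real_, bic = NA_real_)
        else info_criteria(ll, k, fit$n_used)
  tibble(method = fit$method, r = fit$r, R = fit$R,
         pearson_mean = mean(pr), pearson_var = var(pr),
         rms = model_rms(data, fit),
         aic = ic$aic, bic = ic$bic,
         rate_below = below_threshold_rate(data, fit$r),
         n = fit$n_used)
}
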