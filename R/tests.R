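#' Wald test for the piecewise (threshold) structure
#'
#' Tests \eqn{H_0: \beta_1 = \beta_2} from a CLS fit using the asymptotic
#' normality of the estimator:
#' \deqn{T_n^{(1)} = \frac{\mathbf{1}^\top(\hat\beta_1 - \hat\beta_2)}
#'       {\sqrt{A \hat\Sigma A^\top / n}},}
#' with \eqn{A = (\mathbf{1}, -\mathbf{1})} acting on the coefficient block
#' of the sandwich covariance \eqn{\hat\Sigma} (the \eqn{\lambda} coordinate
#' is zero-padded). Under the null the statistic is asymptotically standard
#' normal; the default decision is one-sided, rejecting when the statistic
#' exceeds the upper \eqn{1-\alpha} normal quantile (1.645 at 5%).
#'
#' @param fit A `tvmt_fit` from [fit_cls()] (the sandwich covariance is
#'   required).
#' @param level Nominal size.
#' @param two_sided Use `|T|` against the two-sided critical value instead
#'   of the default one-sided rule.
#' @return A `tvmt_test` object (statistic, reference distribution,
#'   critical value, decision); supports [tidy()].
#' @export
test_piecewise <- function(fit, level = 0.05, two_sided = FALSE) {
  stopifnot(inherits(fit, "tvmt_fit"))
  if (fit$method != "CLS" || is.null(fit$sandwich)) {
    abort("`fit` must be a CLS fit carrying the sandwich covariance.")
  }
  q <- fit$q
  p <- q + 1L
  A <- c(rep(1, p), rep(-1, p), 0)
  num <- sum(fit$coefficients[seq_len(p)] -
               fit$coefficients[p + seq_len(p)])
  denom <- sqrt(drop(A %*% fit$sandwich$Sigma %*% A) / fit$n_used)
  stat <- num / denom
  if (two_sided) {
    crit <- qnorm(1 - level / 2)
    new_tvmt_test(abs(stat), "standard normal (two-sided)", NA_integer_,
                  crit, level, statistic_signed = stat)
  } else {
    crit <- qnorm(1 - level)
    new_tvmt_test(stat, "standard normal (one-sided)", NA_integer_,
                  crit, level)
  }
}

#' Wald test for the presence of explanatory variables
#'
#' Tests \eqn{H_0: \beta_{i,j} = 0} for all slopes
#' (\eqn{i = 1,2;\ j = 1..q}) from a CLS fit:
#' \deqn{T_n^{(2)} = n\,\hat\theta^\top C^\top (C\hat\Sigma C^\top)^{-1}
#'       C\hat\theta,}
#' where `C` extracts the `2q` slope coefficients (a zero column is appended
#' for \eqn{\lambda}). Asymptotically \eqn{\chi^2_{2q}} under the null;
#' rejects above the \eqn{1-\alpha} quantile (5.991 for `q = 1` at 5%).
#'
#' @inheritParams test_piecewise
#' @return A `tvmt_test` object.
#' @export
test_covariates_wald <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "tvmt_fit"))
  if (fit$method != "CLS" || is.null(fit$sandwich)) {
    abort("`fit` must be a CLS fit carrying the sandwich covariance.")
  }
  q <- fit$q
  if (q < 1) abort("no explanatory variables to test (q = 0).")
  p <- q + 1L
  C <- matrix(0, 2 * q, 2 * p + 1)
  for (j in seq_len(q)) {
    C[j, 1 + j] <- 1            # beta1_j
    C[q + j, p + 1 + j] <- 1    # beta2_j
  }
  th <- unname(fit$coefficients)
  Ct <- drop(C %*% th)
  M <- C %*% fit$sandwich$Sigma %*% t(C)
  stat <- fit$n_used * drop(Ct %*% solve(M, Ct))
  df <- 2L * q
  new_tvmt_test(stat, sprintf("chi-square(%d)", df), df,
                qchisq(1 - level, df), level)
}

#' Likelihood-ratio test for the presence of explanatory variables
#'
#' Fits the time-varying model by CML and the constant-coefficient
#' MTTINAR(1) null by [fit_mtt()] at the same `(r, R)`, and forms
#' \eqn{T_n^{(3)} = 2(\hat L - \hat{\tilde L})}. Asymptotically
#' \eqn{\chi^2_{2q}} under the null of no explanatory variables.
#'
#' @inheritParams fit_cls
#' @param level Nominal size.
#' @param fit Optional precomputed CML `tvmt_fit` at `(r, R)` (saves the
#'   refit).
#' @return A `tvmt_test` object; the two fitted log-likelihoods are attached
#'   as `loglik_full` / `loglik_null`.
#' @export
test_covariates_lr <- function(data, r, R = 0, level = 0.05,
                               control = tvmt_control(), fit = NULL) {
  if (is.null(fit)) {
    fit <- fit_cml(data, r, R, control)
  } else {
    stopifnot(inherits(fit, "tvmt_fit"), fit$method == "CML")
  }
  if (fit$q < 1) abort("no explanatory variables to test (q = 0).")
  null_fit <- fit_mtt(data, r, R, control)
  stat <- 2 * (fit$objective - null_fit$logLik)
  df <- 2L * fit$q
  out <- new_tvmt_test(stat, sprintf("chi-square(%d)", df), df,
                       qchisq(1 - level, df), level)
  out$loglik_full <- fit$objective
  out$loglik_null <- null_fit$logLik
  out
}

new_tvmt_test <- function(statistic, null_dist, df, critical, level, ...) {
  structure(
    list(statistic = statistic, null_dist = null_dist, df = df,
         critical_value = critical, level = level,
         reject = statistic > critical, ...),
    class = "tvmt_test"
  )
}

#' @export
print.tvmt_test <- function(x, ...) {
  cat(sprintf("statistic=%.6g dist=%s critical=%.4g level=%.3g reject=%s\n",
              x$statistic, x$null_dist, x$critical_value, x$level,
              x$reject))
  invisible(x)
}

#' @export
tidy.tvmt_test <- function(x, ...) {
  tibble(statistic = x$statistic, null_dist = x$null_dist,
         df = ifelse(is.na(x$df), NA_integer_, x$df),
         critical_value = x$critical_value, level = x$level,
         reject = x$reject)
}
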