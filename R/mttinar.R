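#' Conditional log-likelihood of the MTTINAR(1) null model
#'
#' Constant-coefficient analogue of [cml_loglik()]: thinning probabilities
#' `alpha1` (binomial regime) and `alpha2` (negative-binomial regime) do not
#' depend on covariates.
#'
#' @param par Vector `(alpha1, alpha2, lambda)`.
#' @inheritParams cls_objective
#' @return Scalar log-likelihood.
#' @export
mtt_loglik <- function(par, data, r, R = 0) {
  sm <- series_matrices(data)
  mtt_loglik_raw(par, sm$x, r, R)
}

mtt_loglik_raw <- function(par, x, r, R) {
  n <- length(x)
  mixthin_loglik_cpp(x, rep(par[1], n), rep(par[2], n), par[3], r, R)
}

#' Fit the constant-coefficient MTTINAR(1) model
#'
#' Maximizes the MTTINAR(1) conditional log-likelihood over
#' \eqn{(\alpha_1, \alpha_2) \in (0,1)^2} and \eqn{\lambda > 0} by
#' multi-start L-BFGS-B. This is the null-model fitter for the
#' likelihood-ratio test of explanatory variables ([test_covariates_lr()]).
#'
#' @inheritParams fit_cls
#' @return An object of class `mtt_fit`: `coefficients`
#'   (`alpha1`, `alpha2`, `lambda`), `se` (inverse negative Hessian),
#'   `logLik`, `r`, `R`, `n_used`, `converged`.
#' @export
fit_mtt <- function(data, r, R = 0, control = tvmt_control()) {
  check_threshold(r); check_flag(R)
  sm <- series_matrices(data)
  x <- sm$x
  lam_max <- if (is.null(control$lambda_max)) max(10 * mean(x), 1)
             else control$lambda_max
  eps <- 1e-6
  lower <- c(eps, eps, control$lambda_min)
  upper <- c(1 - eps, 1 - eps, lam_max)
  lam0 <- min(max(mean(x[-1]) - 0.5 * mean(x[-length(x)]), 0.5), lam_max)
  starts <- list(c(0.5, 0.5, lam0), c(0.3, 0.7, lam0), c(0.7, 0.3, lam0))
  n <- length(x)
  fg <- cache_fngr(function(p) {
    sc <- mixthin_score_cpp(x, rep(p[1], n), rep(p[2], n), p[3], r, R)
    list(value = sc$loglik,
         grad = c(sum(sc$dphi[sc$reg1]), sum(sc$dphi[!sc$reg1]),
                  sc$dlambda))
  })
  best <- run_starts(starts, fn = fg$fn, gr = fg$gr,
                     lower = lower, upper = upper,
                     maxit = control$maxit, maximize = TRUE)
  H <- tryCatch(
    optimHess(best$par, function(p) -mtt_loglik_raw(p, x, r, R)),
    error = function(e) NULL
  )
  vc <- hessian_vcov(H, 3)
  nm <- c("alpha1", "alpha2", "lambda")
  dimnames(vc) <- list(nm, nm)
  structure(
    list(coefficients = setNames(best$par, nm),
         se = setNames(sqrt(pmax(diag(vc), 0)), nm),
         vcov = vc, logLik = best$value, r = as.integer(r),
         R = as.integer(R), n_used = length(x) - 1L,
         converged = best$any_converged, data = data),
    class = "mtt_fit"
  )
}

#' @export
print.mtt_fit <- function(x, ...) {
  cat("MTTINAR(1) fit (CML), r =", x$r, ", R =", x$R, "\n")
  print(cbind(estimate = x$coefficients, std.error = x$se))
  cat("logLik:", format(x$logLik), "  n =", x$n_used, "\n")
  invisible(x)
}

#' @export
tidy.mtt_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' @export
glance.mtt_fit <- function(x, ...) {
  ic <- info_criteria(x$logLik, k = 3, n = x$n_used)
  tibble(method = "CML", r = x$r, R = x$R, logLik = x$logLik,
         AIC = ic$aic, BIC = ic$bic, n = x$n_used,
         converged = x$converged)
}
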