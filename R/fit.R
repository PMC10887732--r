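#' Optimizer and fitting controls
#'
#' Box constraints and start strategy for [fit_cls()], [fit_cml()],
#' [fit_mtt()] and [fit_threshold()]. Coefficients are searched over
#' `[-beta_box, beta_box]` per component and \eqn{\lambda} over
#' `[lambda_min, lambda_max]` (default ten times the sample mean count).
#' Every fit starts from a moment-based point (zero slopes, \eqn{\lambda}
#' from the mean one-step residual at \eqn{\phi = 1/2}) plus `extra_starts`
#' random perturbations drawn from the session RNG.
#'
#' @param beta_box Half-width of the coefficient box.
#' @param lambda_min,lambda_max Bounds for the innovation mean; `NULL`
#'   `lambda_max` means `10 * mean(x)`.
#' @param extra_starts Number of additional randomized starts.
#' @param maxit Maximum L-BFGS-B iterations.
#' @param min_occupancy Warn when either regime holds less than this
#'   fraction of the transitions.
#' @return A list of class `tvmt_control`.
#' @export
tvmt_control <- function(beta_box = 20, lambda_min = 1e-6,
                         lambda_max = NULL, extra_starts = 2,
                         maxit = 500, min_occupancy = 0.2) {
  structure(list(beta_box = beta_box, lambda_min = lambda_min,
                 lambda_max = lambda_max, extra_starts = extra_starts,
                 maxit = maxit, min_occupancy = min_occupancy),
            class = "tvmt_control")
}

#' Conditional least squares criterion
#'
#' \eqn{Q(\theta) = \sum_t (X_t - g(\theta, X_{t-1}, Z_t))^2} where `g` is
#' the one-step conditional mean, summed over the transitions of `data`
#' (conditioning on the first observation).
#'
#' @param theta Packed parameter vector `(beta1, beta2, lambda)`.
#' @param data Series tibble with columns `x` and covariates (see
#'   [read_series()] / [simulate_tvmt()]).
#' @param r Integer threshold.
#' @param R Regime-orientation flag.
#' @return Non-negative scalar.
#' @export
cls_objective <- function(theta, data, r, R = 0) {
  sm <- series_matrices(data)
  cls_obj_raw(theta, sm$x, sm$Z, sm$q, r, R)
}

cls_obj_raw <- function(theta, x, Z, q, r, R) {
  th <- theta_split(theta, q)
  cm <- cond_mean_series(x, Z, th$beta1, th$beta2, th$lambda, r, R)
  sum((cm$xt - cm$g)^2)
}

# Analytic gradient of Q: dQ/dtheta = -2 sum U_t dg/dtheta, with
# dg/dbeta_i = phi_i (1 - phi_i) x_{t-1} z I_i and dg/dlambda = 1.
cls_grad_raw <- function(theta, x, Z, q, r, R) {
  th <- theta_split(theta, q)
  cm <- cond_mean_series(x, Z, th$beta1, th$beta2, th$lambda, r, R)
  U <- cm$xt - cm$g
  d1 <- cm$phi1 * (1 - cm$phi1) * cm$xp * cm$i1
  d2 <- cm$phi2 * (1 - cm$phi2) * cm$xp * (!cm$i1)
  g1 <- -2 * drop(crossprod(cm$Zt, U * d1))
  g2 <- -2 * drop(crossprod(cm$Zt, U * d2))
  c(g1, g2, -2 * sum(U))
}

# Per-transition gradient matrix of g and residuals at theta.
cls_score_parts <- function(theta, x, Z, q, r, R) {
  th <- theta_split(theta, q)
  cm <- cond_mean_series(x, Z, th$beta1, th$beta2, th$lambda, r, R)
  D <- cbind(cm$Zt * (cm$phi1 * (1 - cm$phi1) * cm$xp * cm$i1),
             cm$Zt * (cm$phi2 * (1 - cm$phi2) * cm$xp * (!cm$i1)),
             1)
  list(D = D, U = cm$xt - cm$g)
}

#' Sandwich covariance pieces for the CLS estimator
#'
#' Computes \eqn{\hat V_{jk} = n^{-1}\sum_t \partial_j g\, \partial_k g},
#' \eqn{\hat W_{jk} = n^{-1}\sum_t U_t^2 \partial_j g\, \partial_k g}, and
#' \eqn{\hat\Sigma = \hat V^{-1}\hat W\hat V^{-1}}, the estimated asymptotic
#' covariance of \eqn{\sqrt n(\hat\theta_{CLS} - \theta_0)}. Gradients of
#' the conditional mean are analytic.
#'
#' @inheritParams cls_objective
#' @param theta Parameter vector at which to evaluate (usually the CLS
#'   estimate).
#' @return List with matrices `V`, `W`, `Sigma` and the effective sample
#'   size `n_used`.
#' @export
sandwich_covariance <- function(theta, data, r, R = 0) {
  sm <- series_matrices(data)
  sandwich_raw(theta, sm$x, sm$Z, sm$q, r, R)
}

sandwich_raw <- function(theta, x, Z, q, r, R) {
  parts <- cls_score_parts(theta, x, Z, q, r, R)
  n <- length(parts$U)
  V <- crossprod(parts$D) / n
  W <- crossprod(parts$D * parts$U) / n
  kap <- kappa(V, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12) {
    abort(sprintf("V-hat is numerically singular (condition number %.3g).",
                  kap))
  }
  Vi <- solve(V)
  Sigma <- Vi %*% W %*% Vi
  nm <- theta_names(q)
  dimnames(V) <- dimnames(W) <- dimnames(Sigma) <- list(nm, nm)
  list(V = V, W = W, Sigma = Sigma, n_used = n)
}

#' Conditional log-likelihood of the TVMTTINAR(1) model
#'
#' \eqn{L(\theta) = \sum_t \log P(X_t \mid X_{t-1}, Z_t)} over the
#' transitions of `data`, conditioning on the first observation. Individual
#' log terms are floored (at log 1e-300) so degenerate parameter corners
#' stay finite during optimization.
#'
#' @inheritParams cls_objective
#' @return Scalar log-likelihood.
#' @export
cml_loglik <- function(theta, data, r, R = 0) {
  sm <- series_matrices(data)
  cml_loglik_raw(theta, sm$x, sm$Z, sm$q, r, R)
}

cml_loglik_raw <- function(theta, x, Z, q, r, R) {
  th <- theta_split(theta, q)
  phi1 <- clamp_phi(plogis(drop(Z %*% th$beta1)))
  phi2 <- clamp_phi(plogis(drop(Z %*% th$beta2)))
  mixthin_loglik_cpp(x, phi1, phi2, th$lambda, r, R)
}

# keep thinning probabilities strictly inside (0, 1) so score terms with
# 1/phi or 1/(1 - phi) stay finite at extreme linear predictors
clamp_phi <- function(phi) pmin(pmax(phi, 1e-12), 1 - 1e-12)

# log-likelihood and its analytic gradient; score in phi propagated through
# the logistic link (d phi / d beta = phi (1 - phi) z).
cml_value_grad_raw <- function(theta, x, Z, q, r, R) {
  th <- theta_split(theta, q)
  phi1 <- clamp_phi(plogis(drop(Z %*% th$beta1)))
  phi2 <- clamp_phi(plogis(drop(Z %*% th$beta2)))
  sc <- mixthin_score_cpp(x, phi1, phi2, th$lambda, r, R)
  i1 <- sc$reg1
  g1 <- drop(crossprod(Z, sc$dphi * i1 * phi1 * (1 - phi1)))
  g2 <- drop(crossprod(Z, sc$dphi * (!i1) * phi2 * (1 - phi2)))
  list(value = sc$loglik, grad = c(g1, g2, sc$dlambda))
}

# fn/gr pair sharing one evaluation per parameter point.
cache_fngr <- function(fngr) {
  last_par <- NULL
  last <- NULL
  ev <- function(p) {
    if (is.null(last_par) || !identical(p, last_par)) {
      last <<- fngr(p)
      last_par <<- p
    }
    last
  }
  list(fn = function(p) ev(p)$value, gr = function(p) ev(p)$grad)
}

# --- start points -------------------------------------------------------------

moment_start <- function(x, q, ctrl, lam_max) {
  n <- length(x)
  lam0 <- mean(x[-1]) - 0.5 * mean(x[-n])
  lam0 <- min(max(lam0, 0.5), lam_max)
  c(rep(0, 2 * (q + 1)), lam0)
}

start_list <- function(x, q, ctrl, lam_max, extra = NULL) {
  base <- moment_start(x, q, ctrl, lam_max)
  starts <- list(base)
  if (!is.null(extra)) starts <- c(starts, extra)
  if (ctrl$extra_starts > 0) {
    for (i in seq_len(ctrl$extra_starts)) {
      s <- base
      s[seq_len(2 * (q + 1))] <- runif(2 * (q + 1), -1, 1)
      s[length(s)] <- min(max(base[length(s)] * runif(1, 0.5, 2),
                              ctrl$lambda_min), lam_max)
      starts <- c(starts, list(s))
    }
  }
  starts
}

run_starts <- function(starts, fn, gr, lower, upper, maxit, maximize = FALSE) {
  best <- NULL
  ok <- FALSE
  sgn <- if (maximize) -1 else 1
  wrap_fn <- function(p) sgn * fn(p)
  wrap_gr <- if (is.null(gr)) NULL else function(p) sgn * gr(p)
  for (s in starts) {
    res <- tryCatch(
      optim(s, wrap_fn, wrap_gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ok <- ok || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) abort("all optimizer starts failed.")
  best$value <- sgn * best$value
  best$any_converged <- ok
  best
}

check_occupancy <- function(x, r, R, ctrl) {
  n <- length(x)
  i1 <- regime_indicator(x[-n], r, R)
  frac <- mean(i1)
  if (min(frac, 1 - frac) < ctrl$min_occupancy) {
    warn(sprintf(
      "regime occupancy %.1f%% / %.1f%% below the %.0f%% guideline at r = %d.",
      100 * frac, 100 * (1 - frac), 100 * ctrl$min_occupancy, r))
  }
}

# --- fitting ------------------------------------------------------------------

#' Fit a TVMTTINAR(1) model
#'
#' `fit_cls()` minimizes the conditional least squares criterion
#' [cls_objective()] and attaches the sandwich covariance estimate
#' (\eqn{\hat V^{-1}\hat W\hat V^{-1}}); `fit_cml()` maximizes the
#' conditional log-likelihood [cml_loglik()] and estimates the covariance by
#' the inverse negative Hessian. Both use multi-start box-constrained
#' L-BFGS-B; `fit_cml()` additionally starts from the CLS estimate.
#'
#' @param data Series tibble: column `x` plus one column per explanatory
#'   variable (every non-`t`, non-`x` column is used, in order).
#' @param r Known (or previously estimated) integer threshold.
#' @param R Regime-orientation flag (0 or 1).
#' @param control A [tvmt_control()].
#' @param cls_start Optional precomputed CLS fit (or parameter vector) used
#'   as a start for `fit_cml()`.
#' @return An object of class `tvmt_fit` with elements `coefficients`,
#'   `se`, `vcov` (covariance of the estimate), `method`, `objective`
#'   (criterion value at the optimum), `r`, `R`, `n_used`, `converged`; CLS
#'   fits also carry `sandwich` (the `V`, `W`, `Sigma` matrices). Supports
#'   [tidy()], [glance()], [residuals()][residuals.tvmt_fit] and
#'   [autoplot()].
#' @examples
#' m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
#' set.seed(1)
#' d <- simulate_tvmt(m, 300, covariates = list(cov_iid_normal()))
#' fit <- fit_cls(d, r = 6)
#' tidy(fit)
#' @export
fit_cls <- function(data, r, R = 0, control = tvmt_control()) {
  sm <- series_matrices(data)
  fit_cls_raw(sm$x, sm$Z, sm$q, r, R, control, data = data)
}

fit_cls_raw <- function(x, Z, q, r, R, ctrl, extra = NULL, data = NULL,
                        quiet = FALSE) {
  check_threshold(r); check_flag(R)
  if (length(x) < 2) abort("need at least 2 observations.")
  if (!quiet) check_occupancy(x, r, R, ctrl)
  lam_max <- if (is.null(ctrl$lambda_max)) max(10 * mean(x), 1)
             else ctrl$lambda_max
  p <- 2 * (q + 1)
  lower <- c(rep(-ctrl$beta_box, p), ctrl$lambda_min)
  upper <- c(rep(ctrl$beta_box, p), lam_max)
  starts <- start_list(x, q, ctrl, lam_max, extra)
  best <- run_starts(starts,
                     fn = function(th) cls_obj_raw(th, x, Z, q, r, R),
                     gr = function(th) cls_grad_raw(th, x, Z, q, r, R),
                     lower = lower, upper = upper, maxit = ctrl$maxit)
  # a nearly empty regime (e.g. extreme grid candidates) makes V-hat
  # singular; keep the point estimate usable and flag the covariance
  sw <- tryCatch(sandwich_raw(best$par, x, Z, q, r, R),
                 error = function(e) {
                   if (!quiet) warn(conditionMessage(e))
                   NULL
                 })
  pdim <- 2 * (q + 1) + 1
  vc <- if (is.null(sw)) {
    matrix(NA_real_, pdim, pdim,
           dimnames = list(theta_names(q), theta_names(q)))
  } else {
    sw$Sigma / sw$n_used
  }
  new_tvmt_fit(best$par, q, r, R, method = "CLS",
               objective = best$value, vcov = vc, sandwich = sw,
               n_used = length(x) - 1L, converged = best$any_converged,
               data = data)
}

#' @rdname fit_cls
#' @export
fit_cml <- function(data, r, R = 0, control = tvmt_control(),
                    cls_start = NULL) {
  sm <- series_matrices(data)
  fit_cml_raw(sm$x, sm$Z, sm$q, r, R, control, cls_start = cls_start,
              data = data)
}

fit_cml_raw <- function(x, Z, q, r, R, ctrl, cls_start = NULL, extra = NULL,
                        data = NULL, quiet = FALSE) {
  check_threshold(r); check_flag(R)
  if (length(x) < 2) abort("need at least 2 observations.")
  if (!quiet) check_occupancy(x, r, R, ctrl)
  lam_max <- if (is.null(ctrl$lambda_max)) max(10 * mean(x), 1)
             else ctrl$lambda_max
  p <- 2 * (q + 1)
  lower <- c(rep(-ctrl$beta_box, p), ctrl$lambda_min)
  upper <- c(rep(ctrl$beta_box, p), lam_max)
  if (is.null(cls_start)) {
    cls_start <- fit_cls_raw(x, Z, q, r, R, ctrl, quiet = TRUE)
  }
  cls_par <- if (inherits(cls_start, "tvmt_fit")) {
    unname(cls_start$coefficients)
  } else {
    as.numeric(cls_start)
  }
  cls_par <- pmin(pmax(cls_par, lower), upper)
  starts <- start_list(x, q, ctrl, lam_max, extra = c(list(cls_par), extra))
  fg <- cache_fngr(function(th) cml_value_grad_raw(th, x, Z, q, r, R))
  best <- run_starts(starts, fn = fg$fn, gr = fg$gr,
                     lower = lower, upper = upper,
                     maxit = ctrl$maxit, maximize = TRUE)
  H <- tryCatch(
    optimHess(best$par, function(th) -cml_loglik_raw(th, x, Z, q, r, R)),
    error = function(e) NULL
  )
  vc <- hessian_vcov(H, 2 * (q + 1) + 1)
  dimnames(vc) <- list(theta_names(q), theta_names(q))
  new_tvmt_fit(best$par, q, r, R, method = "CML",
               objective = best$value, vcov = vc, sandwich = NULL,
               n_used = length(x) - 1L, converged = best$any_converged,
               data = data)
}

hessian_vcov <- function(H, p) {
  if (is.null(H)) return(matrix(NA_real_, p, p))
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  if (all(is.finite(diag(vc))) && any(diag(vc) < 0)) {
    warn("negative diagonal in inverse Hessian; SEs set to NA there.")
    diag(vc)[diag(vc) < 0] <- NA_real_
  }
  vc
}

new_tvmt_fit <- function(theta, q, r, R, method, objective, vcov, sandwich,
                         n_used, converged, data = NULL, profile = NULL) {
  nm <- theta_names(q)
  se <- sqrt(pmax(diag(vcov), 0))
  structure(
    list(coefficients = setNames(theta, nm), se = setNames(se, nm),
         vcov = vcov, sandwich = sandwich, method = method,
         objective = objective, r = as.integer(r), R = as.integer(R),
         q = q, n_used = n_used, converged = converged,
         data = data, profile = profile),
    class = "tvmt_fit"
  )
}

#' Two-step grid search for the integer threshold
#'
#' Step 1 scans every integer `r` between the empirical 10th and 90th
#' quantiles of the counts, fitting the model at each candidate and scoring
#' it by the method's criterion (Q minimized for CLS, L maximized for CML);
#' ties go to the smallest candidate. Step 2 returns the fit at the selected
#' threshold; the full objective profile is attached as `$profile` so ties
#' and near-ties are visible.
#'
#' @inheritParams fit_cls
#' @param method `"cml"` or `"cls"`.
#' @return A `tvmt_fit` whose `r` is the estimated threshold, with a
#'   `profile` tibble (`r`, `objective`).
#' @export
fit_threshold <- function(data, R = 0, method = c("cml", "cls"),
                          control = tvmt_control()) {
  method <- match.arg(method)
  sm <- series_matrices(data)
  cand <- threshold_candidates(sm$x)
  fits <- vector("list", length(cand))
  warm_cls <- NULL
  warm_cml <- NULL
  for (i in seq_along(cand)) {
    r <- cand[i]
    cls_extra <- if (is.null(warm_cls)) NULL else list(warm_cls)
    f_cls <- fit_cls_raw(sm$x, sm$Z, sm$q, r, R, control, extra = cls_extra,
                         quiet = TRUE)
    warm_cls <- unname(f_cls$coefficients)
    if (method == "cls") {
      fits[[i]] <- f_cls
    } else {
      cml_extra <- if (is.null(warm_cml)) NULL else list(warm_cml)
      f <- fit_cml_raw(sm$x, sm$Z, sm$q, r, R, control, cls_start = f_cls,
                       extra = cml_extra, quiet = TRUE)
      warm_cml <- unname(f$coefficients)
      fits[[i]] <- f
    }
  }
  obj <- vapply(fits, function(f) f$objective, numeric(1))
  pick <- if (method == "cls") which.min(obj) else which.max(obj)
  best <- fits[[pick]]
  best$profile <- tibble(r = cand, objective = obj)
  best$data <- data
  check_occupancy(sm$x, best$r, R, control)
  best
}

#' Integer threshold candidates between the empirical deciles
#'
#' @param x Count vector.
#' @return Integer vector of candidate thresholds (10th to 90th empirical
#'   quantile, order-statistic convention).
#' @export
threshold_candidates <- function(x) {
  qs <- quantile(x, c(0.1, 0.9), type = 1, names = FALSE)
  cand <- seq.int(ceiling(qs[1]), floor(qs[2]))
  if (length(cand) < 1) abort("empty threshold candidate set.")
  as.integer(cand)
}
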