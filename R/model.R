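#' Specify a time-varying mixture-thinning threshold INAR(1) model
#'
#' A TVMTTINAR(1) process evolves as
#' \deqn{X_t = (\phi_{1,t} \circ X_{t-1})\, I_{1,t} +
#'             (\phi_{2,t} * X_{t-1})\, I_{2,t} + \epsilon_t,}
#' where \eqn{\circ} is binomial thinning, \eqn{*} is negative-binomial
#' thinning, \eqn{\epsilon_t \sim} Poisson(\eqn{\lambda}), and the thinning
#' probabilities follow a logistic link in observable explanatory variables,
#' \eqn{\mathrm{logit}\,\phi_{i,t} = Z_t^\top \beta_i}. The regime indicator
#' \eqn{I_{1,t}} is \eqn{I\{X_{t-1} \le r\}} when `R = 0` and
#' \eqn{I\{X_{t-1} > r\}} when `R = 1`, so `R` selects which operator acts
#' below the integer threshold `r`.
#'
#' @param beta1,beta2 Numeric coefficient vectors of length `q + 1`
#'   (intercept first) for the binomial-thinning and negative-binomial-thinning
#'   regimes respectively.
#' @param lambda Positive Poisson innovation mean.
#' @param r Non-negative integer threshold on the lagged count.
#' @param R Regime-orientation flag, 0 or 1 (see Details).
#'
#' @return An object of class `tvmt_model`.
#' @examples
#' m <- tvmt_model(beta1 = c(0.1, 0.3), beta2 = c(-0.5, -0.6),
#'                 lambda = 5, r = 6)
#' m
#' @export
tvmt_model <- function(beta1, beta2, lambda, r, R = 0) {
  beta1 <- as.numeric(beta1)
  beta2 <- as.numeric(beta2)
  if (length(beta1) != length(beta2)) {
    abort("`beta1` and `beta2` must have the same length (q + 1).")
  }
  if (length(beta1) < 1) abort("coefficient vectors must include an intercept.")
  if (!is.numeric(lambda) || length(lambda) != 1 || !is.finite(lambda) ||
      lambda <= 0) {
    abort("`lambda` must be a single positive number.")
  }
  check_threshold(r)
  check_flag(R)
  structure(
    list(beta1 = beta1, beta2 = beta2, lambda = lambda,
         r = as.integer(r), R = as.integer(R), q = length(beta1) - 1L),
    class = "tvmt_model"
  )
}

#' Specify a constant-coefficient mixture-thinning threshold INAR(1) model
#'
#' The MTTINAR(1) process is the covariate-free special case of
#' [tvmt_model()]: thinning probabilities are constants
#' \eqn{\alpha_1, \alpha_2 \in (0,1)} instead of logistic functions of
#' explanatory variables. It is the null model when testing whether
#' explanatory variables matter.
#'
#' @param alpha1,alpha2 Thinning parameters in (0, 1) for the binomial and
#'   negative-binomial regimes.
#' @param lambda Positive Poisson innovation mean.
#' @inheritParams tvmt_model
#' @return An object of class `mtt_model`.
#' @examples
#' mtt_model(0.6225, 0.4502, lambda = 5, r = 6, R = 0)
#' @export
mtt_model <- function(alpha1, alpha2, lambda, r, R = 0) {
  for (a in list(alpha1, alpha2)) {
    if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
      abort("`alpha1` and `alpha2` must lie strictly in (0, 1).")
    }
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    abort("`lambda` must be a single positive number.")
  }
  check_threshold(r)
  check_flag(R)
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, lambda = lambda,
         r = as.integer(r), R = as.integer(R)),
    class = "mtt_model"
  )
}

check_threshold <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0 ||
      r != floor(r)) {
    abort("`r` must be a single non-negative integer.")
  }
  invisible(r)
}

check_flag <- function(R) {
  if (!(length(R) == 1 && R %in% c(0, 1))) abort("`R` must be 0 or 1.")
  invisible(R)
}

#' @export
print.tvmt_model <- function(x, ...) {
  cat("TVMTTINAR(1) model (R =", x$R, ")\n")
  cat("  beta1 (binomial-thinning regime): ",
      paste(format(x$beta1), collapse = " "), "\n")
  cat("  beta2 (NB-thinning regime):       ",
      paste(format(x$beta2), collapse = " "), "\n")
  cat("  lambda =", format(x$lambda), "  r =", x$r,
      "  q =", x$q, "\n")
  invisible(x)
}

#' @export
print.mtt_model <- function(x, ...) {
  cat("MTTINAR(1) model (R =", x$R, ")\n")
  cat("  alpha1 =", format(x$alpha1), " alpha2 =", format(x$alpha2),
      " lambda =", format(x$lambda), " r =", x$r, "\n")
  invisible(x)
}

#' Logistic link between covariates and thinning probability
#'
#' Maps a linear predictor \eqn{Z_t^\top \beta} to a thinning probability in
#' (0, 1). Numerically stable for arbitrarily large linear predictors.
#'
#' @param z Covariate row (including the leading 1 for the intercept), or a
#'   matrix with one row per time point.
#' @param beta Coefficient vector of matching length.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @examples
#' logistic_link(c(1, 0), c(0.1, 0.3))
#' @export
logistic_link <- function(z, beta) {
  if (is.matrix(z)) {
    if (ncol(z) != length(beta)) abort("ncol(z) must equal length(beta).")
    return(plogis(drop(z %*% beta)))
  }
  if (length(z) != length(beta)) {
    abort("`z` and `beta` must have the same length.")
  }
  plogis(sum(z * beta))
}

#' Regime membership of a lagged count
#'
#' Returns the regime-1 indicator \eqn{I_{1,t}} for lagged counts: with
#' `R = 0` regime 1 (binomial thinning, coefficients `beta1`) holds when
#' `x_prev <= r`; with `R = 1` the branches swap.
#'
#' @param x_prev Non-negative lagged count(s).
#' @inheritParams tvmt_model
#' @return Logical vector: `TRUE` where regime 1 applies.
#' @examples
#' regime_indicator(c(5, 6, 7), r = 6, R = 0)
#' @export
regime_indicator <- function(x_prev, r, R = 0) {
  check_flag(R)
  below <- x_prev <= r
  if (R == 0) below else !below
}

# Coerce fitted objects / specs to a tvmt_model for diagnostics code.
as_tvmt_model <- function(object) {
  if (inherits(object, "tvmt_model")) return(object)
  if (inherits(object, "tvmt_fit")) {
    th <- theta_split(object$coefficients, object$q)
    return(tvmt_model(th$beta1, th$beta2, th$lambda, object$r, object$R))
  }
  abort("cannot interpret `object` as a TVMTTINAR(1) model.")
}

# split theta = (beta1, beta2, lambda) given q
theta_split <- function(theta, q) {
  p <- q + 1L
  list(beta1 = theta[seq_len(p)],
       beta2 = theta[p + seq_len(p)],
       lambda = theta[[2 * p + 1]])
}

theta_names <- function(q) {
  c(paste0("beta1_", 0:q), paste0("beta2_", 0:q), "lambda")
}
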