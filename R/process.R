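#' One-step transition probability of the TVMTTINAR(1) process
#'
#' Probability of moving from `x_prev` to `x` given the covariate row `z`,
#' i.e. the convolution of the regime's thinning distribution applied to
#' `x_prev` with a Poisson(\eqn{\lambda}) innovation. The regime (binomial
#' vs negative-binomial thinning, coefficients `beta1` vs `beta2`) is decided
#' by [regime_indicator()].
#'
#' @param x_prev Previous count.
#' @param x Current count; may be a vector.
#' @param z Covariate row `(1, z1, ..., zq)`.
#' @param model A [tvmt_model()].
#' @return Probability vector, one entry per element of `x`.
#' @examples
#' m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
#' transition_pmf(0, 0:4, z = c(1, 0), m)   # Poisson(5) pmf
#' @export
transition_pmf <- function(x_prev, x, z, model) {
  stopifnot(inherits(model, "tvmt_model"))
  if (x_prev < 0 || any(x < 0)) abort("counts must be non-negative.")
  i1 <- regime_indicator(x_prev, model$r, model$R)
  if (i1) {
    phi <- logistic_link(z, model$beta1)
    vapply(x, function(xt) {
      if (x_prev == 0) return(dpois(xt, model$lambda))
      m <- 0:min(x_prev, xt)
      sum(dbinom(m, x_prev, phi) * dpois(xt - m, model$lambda))
    }, numeric(1))
  } else {
    phi <- logistic_link(z, model$beta2)
    vapply(x, function(xt) {
      if (x_prev == 0) return(dpois(xt, model$lambda))
      m <- 0:xt
      sum(dnbinom(m, size = x_prev, prob = 1 / (1 + phi)) *
            dpois(xt - m, model$lambda))
    }, numeric(1))
  }
}

#' Conditional mean and variance of one step
#'
#' Given the lagged count and covariate row, the one-step mean is
#' \eqn{\phi_{i,t} X_{t-1} + \lambda} with \eqn{i} the active regime; the
#' variance is \eqn{\phi_{1,t}(1-\phi_{1,t}) X_{t-1} + \lambda} under
#' binomial thinning and \eqn{\phi_{2,t}(1+\phi_{2,t}) X_{t-1} + \lambda}
#' under negative-binomial thinning.
#'
#' @inheritParams transition_pmf
#' @return Numeric scalar (or vector if `x_prev` is a vector and `z` a
#'   matrix with matching rows).
#' @examples
#' m <- tvmt_model(c(0.1, 0), c(-0.5, 0), lambda = 5, r = 6)
#' cond_mean(4, c(1, 0), m)
#' @export
cond_mean <- function(x_prev, z, model) {
  stopifnot(inherits(model, "tvmt_model"))
  z <- rbind(z)
  i1 <- regime_indicator(x_prev, model$r, model$R)
  phi1 <- logistic_link(z, model$beta1)
  phi2 <- logistic_link(z, model$beta2)
  ifelse(i1, phi1, phi2) * x_prev + model$lambda
}

#' @rdname cond_mean
#' @export
cond_var <- function(x_prev, z, model) {
  stopifnot(inherits(model, "tvmt_model"))
  z <- rbind(z)
  i1 <- regime_indicator(x_prev, model$r, model$R)
  phi1 <- logistic_link(z, model$beta1)
  phi2 <- logistic_link(z, model$beta2)
  ifelse(i1, phi1 * (1 - phi1), phi2 * (1 + phi2)) * x_prev + model$lambda
}

# --- internal series plumbing -------------------------------------------------

# Extract (x, Z) from a series tibble/data.frame: column `x` holds counts,
# every column except `t` and `x` is a covariate; an intercept column of ones
# is prepended.  Returns list(x = integer vector, Z = n x (q+1) matrix).
series_matrices <- function(data, q = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!"x" %in% names(data)) abort("`data` must contain a column `x`.")
  x <- data$x
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort("column `x` must hold non-negative integers.")
  }
  zcols <- setdiff(names(data), c("t", "x"))
  Z <- cbind(1, as.matrix(data[zcols]))
  colnames(Z) <- c("(Intercept)", zcols)
  if (!is.null(q) && ncol(Z) != q + 1) {
    abort(sprintf("expected %d covariate column(s), found %d.",
                  q, ncol(Z) - 1))
  }
  list(x = as.integer(x), Z = Z, q = ncol(Z) - 1L)
}

# Per-row conditional means for transitions 2..n (row t uses x[t-1], Z[t, ]).
cond_mean_series <- function(x, Z, beta1, beta2, lambda, r, R) {
  n <- length(x)
  xp <- x[-n]
  Zt <- Z[-1, , drop = FALSE]
  i1 <- regime_indicator(xp, r, R)
  phi1 <- plogis(drop(Zt %*% beta1))
  phi2 <- plogis(drop(Zt %*% beta2))
  list(g = ifelse(i1, phi1, phi2) * xp + lambda,
       xp = xp, xt = x[-1], i1 = i1, phi1 = phi1, phi2 = phi2, Zt = Zt)
}
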