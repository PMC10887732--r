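# Brute-force oracles, independent of the package's pmf code paths:
# everything is written out with factorials / gamma functions directly.

# thinning-plus-Poisson convolution pmf by direct enumeration
oracle_transition <- function(x_prev, x, phi, lambda,
                              operator = c("binomial", "nbinom")) {
  operator <- match.arg(operator)
  pois <- function(k) exp(-lambda) * lambda^k / factorial(k)
  if (x_prev == 0) return(pois(x))
  if (operator == "binomial") {
    m <- 0:min(x_prev, x)
    thin <- factorial(x_prev) / (factorial(m) * factorial(x_prev - m)) *
      phi^m * (1 - phi)^(x_prev - m)
  } else {
    m <- 0:x
    thin <- gamma(x_prev + m) / (gamma(x_prev) * gamma(m + 1)) *
      phi^m / (1 + phi)^(x_prev + m)
  }
  sum(thin * pois(x - m))
}

# model with q = 0 whose regime probabilities are exactly (phi1, phi2)
model_with_phi <- function(phi1, phi2, lambda, r, R = 0) {
  tvmt_model(qlogis(phi1), qlogis(phi2), lambda, r, R)
}

# deterministic tiny series tibble (q = 1 covariate)
toy_series <- function(x, z) {
  tibble::tibble(t = seq_along(x), x = x, z1 = z)
}

# central finite differences of a scalar function
fd_grad <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}
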