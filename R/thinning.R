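#' Thinning-operator probability mass functions
#'
#' `thin_binom_pmf()` is the pmf of binomial thinning
#' \eqn{\phi \circ x}, i.e. Binomial(`x`, `phi`) evaluated at `m`.
#' `thin_nbinom_pmf()` is the pmf of negative-binomial thinning
#' \eqn{\phi * x}, the sum of `x` i.i.d. geometric variables on
#' \eqn{\{0,1,\dots\}} with success probability \eqn{1/(1+\phi)}:
#' \deqn{P(m) = \frac{\Gamma(x+m)}{\Gamma(x)\,\Gamma(m+1)}
#'        \frac{\phi^m}{(1+\phi)^{x+m}}, \quad x \ge 1,}
#' with the convention \eqn{\phi * 0 \equiv 0}. Both are evaluated in
#' log-space via the stats d-functions.
#'
#' @param m Value(s) at which to evaluate the pmf.
#' @param x Count being thinned.
#' @param phi Thinning parameter in (0, 1).
#' @param log Return log-probabilities?
#' @return Probability (or log-probability) vector.
#' @examples
#' thin_binom_pmf(2, 5, 0.3)
#' thin_nbinom_pmf(0:5, 3, 0.4)
#' @export
thin_binom_pmf <- function(m, x, phi, log = FALSE) {
  check_phi(phi)
  dbinom(m, size = x, prob = phi, log = log)
}

#' @rdname thin_binom_pmf
#' @export
thin_nbinom_pmf <- function(m, x, phi, log = FALSE) {
  check_phi(phi)
  if (x == 0) {
    p <- as.numeric(m == 0)
    return(if (log) log(p) else p)
  }
  dnbinom(m, size = x, prob = 1 / (1 + phi), log = log)
}

#' Draw from the thinning operators
#'
#' `thin_binom_sample()` draws \eqn{\phi \circ x} (Binomial);
#' `thin_nbinom_sample()` draws \eqn{\phi * x} (sum of `x` geometrics,
#' i.e. negative binomial with size `x` and success probability
#' \eqn{1/(1+\phi)}). Vectorized over `x`; uses the R session RNG so draws
#' are reproducible under [set.seed()].
#'
#' @param x Count(s) being thinned.
#' @param phi Thinning parameter in (0, 1).
#' @return Integer draw(s), one per element of `x`.
#' @examples
#' set.seed(1)
#' thin_binom_sample(c(10, 0, 3), 0.3)
#' thin_nbinom_sample(5, 0.4)
#' @export
thin_binom_sample <- function(x, phi) {
  check_phi(phi)
  rbinom(length(x), size = x, prob = phi)
}

#' @rdname thin_binom_sample
#' @export
thin_nbinom_sample <- function(x, phi) {
  check_phi(phi)
  out <- integer(length(x))
  pos <- x > 0
  if (any(pos)) {
    out[pos] <- rnbinom(sum(pos), size = x[pos], prob = 1 / (1 + phi))
  }
  out
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || any(phi <= 0) || any(phi >= 1)) {
    abort("`phi` must lie strictly in (0, 1).")
  }
  invisible(phi)
}
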