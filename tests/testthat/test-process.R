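test_that("regime indicator honours the threshold boundary and the R swap", {
  expect_true(regime_indicator(6, r = 6, R = 0))
  expect_false(regime_indicator(7, r = 6, R = 0))
  expect_false(regime_indicator(6, r = 6, R = 1))
  expect_true(regime_indicator(7, r = 6, R = 1))
  x <- 0:15
  expect_identical(regime_indicator(x, 6, 1), !regime_indicator(x, 6, 0))
})

test_that("transition pmf equals the brute-force convolution oracle", {
  for (phi in c(0.1, 0.5, 0.9)) {
    for (lam in c(0.5, 5)) {
      m0 <- model_with_phi(phi, phi, lam, r = 6, R = 0)
      for (xp in c(0, 1, 5, 12)) {
        op <- if (regime_indicator(xp, 6, 0)) "binomial" else "nbinom"
        for (xt in c(0, 2, 7)) {
          expect_equal(transition_pmf(xp, xt, z = 1, m0),
                       oracle_transition(xp, xt, phi, lam, op),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # the frozen spot value for a regime-1 step
  expect_equal(transition_pmf(3, 2, 1, model_with_phi(0.5, 0.5, 1, r = 6)),
               0.8125 * exp(-1), tolerance = 1e-12)
})

test_that("transition pmf is a normalized distribution on both branches", {
  for (phi in c(0.1, 0.5, 0.9)) {
    for (lam in c(0.5, 5)) {
      for (R in 0:1) {
        m0 <- model_with_phi(phi, phi, lam, r = 6, R = R)
        for (xp in c(0, 1, 5, 12)) {
          xmax <- 30 + 4 * xp + ceiling(10 * lam)
          expect_equal(sum(transition_pmf(xp, 0:xmax, 1, m0)), 1,
                       tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("x_prev = 0 reduces to the Poisson innovation in both regimes", {
  m0 <- model_with_phi(0.7, 0.2, 3, r = 0, R = 0)  # 0 <= r: regime 1
  m1 <- model_with_phi(0.7, 0.2, 3, r = 0, R = 1)  # swapped: regime 2
  expect_equal(transition_pmf(0, 0:12, 1, m0), dpois(0:12, 3))
  expect_equal(transition_pmf(0, 0:12, 1, m1), dpois(0:12, 3))
})

test_that("conditional moments match the closed forms and the sampler", {
  m <- model_with_phi(0.525, 0.4, 5, r = 6, R = 0)
  expect_equal(cond_mean(0, 1, m), 5)
  expect_equal(cond_mean(4, 1, m), 0.525 * 4 + 5)
  m2 <- model_with_phi(0.5, 0.4, 2, r = 2, R = 0)
  expect_equal(cond_var(3, 1, m2), 0.4 * 1.4 * 3 + 2)  # regime 2
  expect_equal(cond_var(0, 1, m2), 2)

  # Monte Carlo one-step check of both regimes (also validates the samplers)
  set.seed(5)
  n <- 1e5
  for (xp in c(4, 9)) {
    mm <- model_with_phi(0.6, 0.35, 3, r = 6, R = 0)
    i1 <- regime_indicator(xp, 6, 0)
    draws <- (if (i1) thin_binom_sample(rep(xp, n), 0.6)
              else thin_nbinom_sample(rep(xp, n), 0.35)) + rpois(n, 3)
    mu <- cond_mean(xp, 1, mm)
    v <- cond_var(xp, 1, mm)
    expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / n))
    expect_lt(abs(var(draws) - v), 3 * v * sqrt(2 / n) * 2)
    # empirical one-step pmf vs transition pmf, total variation
    emp <- tabulate(draws + 1, nbins = max(draws) + 1) / n
    theo <- transition_pmf(xp, seq_along(emp) - 1, 1, mm)
    expect_lt(0.5 * sum(abs(emp - theo)) + 0.5 * (1 - sum(theo)), 0.01)
  }
})

test_that("simulation is reproducible, non-negative, and needs enough covariates", {
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  set.seed(9); d1 <- simulate_tvmt(m, 200, list(cov_iid_normal()))
  set.seed(9); d2 <- simulate_tvmt(m, 200, list(cov_iid_normal()))
  expect_identical(d1, d2)
  expect_true(all(d1$x >= 0))
  expect_equal(nrow(d1), 200)
  expect_error(simulate_tvmt(m, 200, matrix(rnorm(100), 100, 1)), "rows")
})

test_that("long-run simulated mean is self-consistent and satisfies the
           mixture moment identity", {
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  set.seed(21)
  d <- simulate_tvmt(m, 4e4, list(cov_iid_normal()))
  set.seed(2188)
  d2 <- simulate_tvmt(m, 8e4, list(cov_iid_normal()))
  # autocorrelated series: scale the naive SE by an effective-sample factor
  se <- sd(d$x) / sqrt(length(d$x) / 10)
  expect_lt(abs(mean(d$x) - mean(d2$x)), 3 * se)

  # E(X) = sum_i p_i phi_i mu_i + lambda from sample estimates
  x <- d2$x; z <- cbind(1, d2$z1)
  xp <- x[-length(x)]; xt <- x[-1]
  i1 <- regime_indicator(xp, 6, 0)
  phi1_bar <- mean(plogis(drop(z %*% m$beta1)))
  phi2_bar <- mean(plogis(drop(z %*% m$beta2)))
  p1 <- mean(i1)
  mu1 <- mean(xp[i1]); mu2 <- mean(xp[!i1])
  lhs <- mean(xt)
  rhs <- p1 * phi1_bar * mu1 + (1 - p1) * phi2_bar * mu2 + m$lambda
  expect_lt(abs(lhs - rhs), 3 * sd(x) / sqrt(length(x) / 10))
})
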