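make_cls_fit <- function(seed = 1, n = 600) {
  set.seed(seed)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, n, list(cov_iid_normal()))
  fit_cls(d, 6)
}

test_that("piecewise Wald statistic is zero at equal blocks and antisymmetric", {
  fit <- make_cls_fit()
  # force equal coefficient blocks: numerator vanishes exactly
  fit0 <- fit
  fit0$coefficients[3:4] <- fit0$coefficients[1:2]
  expect_equal(test_piecewise(fit0)$statistic, 0)
  expect_false(test_piecewise(fit0)$reject)

  # swapping the fitted regime blocks (and the matching rows/cols of Sigma)
  # negates the statistic and leaves its denominator unchanged
  perm <- c(3, 4, 1, 2, 5)
  fit_sw <- fit
  fit_sw$coefficients <- fit$coefficients[perm]
  fit_sw$sandwich$Sigma <- fit$sandwich$Sigma[perm, perm]
  t1 <- test_piecewise(fit)$statistic
  t2 <- test_piecewise(fit_sw)$statistic
  expect_equal(t2, -t1, tolerance = 1e-12)
})

test_that("piecewise Wald decision rules match the stated critical values", {
  fit <- make_cls_fit(2)
  res <- test_piecewise(fit)
  expect_equal(res$critical_value, qnorm(0.95), tolerance = 1e-12)
  expect_identical(res$reject, res$statistic > res$critical_value)
  res2 <- test_piecewise(fit, two_sided = TRUE)
  expect_equal(res2$critical_value, qnorm(0.975), tolerance = 1e-12)
  cml <- fit_cml(fit$data, 6, cls_start = fit)
  expect_error(test_piecewise(cml), "CLS")
})

test_that("covariate Wald statistic vanishes at zero slopes and ignores
           covariate ordering", {
  fit <- make_cls_fit(3)
  fit0 <- fit
  fit0$coefficients[c(2, 4)] <- 0
  expect_equal(test_covariates_wald(fit0)$statistic, 0)

  # q = 2 fit: permuting the two covariates leaves the statistic unchanged
  set.seed(4)
  m <- tvmt_model(c(0.1, 0.5, 0.3), c(-0.3, -0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 600, list(cov_ar1(0.5), cov_seasonal()))
  ctrl <- tvmt_control(extra_starts = 0)
  f1 <- fit_cls(d, 6, 0, ctrl)
  d2 <- dplyr::select(d, t, x, z1 = z2, z2 = z1)
  f2 <- fit_cls(d2, 6, 0, ctrl)
  s1 <- test_covariates_wald(f1)$statistic
  s2 <- test_covariates_wald(f2)$statistic
  expect_equal(s1, s2, tolerance = 1e-6)
  expect_equal(test_covariates_wald(f1)$critical_value, qchisq(0.95, 4))
})

test_that("MTTINAR likelihood matches a brute-force convolution oracle", {
  x <- c(2L, 8L, 0L, 3L, 5L)
  d <- tibble::tibble(t = 1:5, x = x)
  a1 <- 0.6; a2 <- 0.35; lam <- 1.7; r <- 4
  ll <- 0
  for (t in 2:5) {
    xp <- x[t - 1]
    op <- if (xp <= r) "binomial" else "nbinom"
    phi <- if (xp <= r) a1 else a2
    ll <- ll + log(oracle_transition(xp, x[t], phi, lam, op))
  }
  expect_equal(mtt_loglik(c(a1, a2, lam), d, r, 0), ll, tolerance = 1e-10)
  # x_prev = 0 rows contribute the Poisson innovation likelihood only
  d0 <- tibble::tibble(t = 1:2, x = c(0L, 3L))
  expect_equal(mtt_loglik(c(a1, a2, lam), d0, r, 0),
               dpois(3, lam, log = TRUE), tolerance = 1e-12)
})

test_that("MTTINAR fitter recovers constant-coefficient truth", {
  set.seed(5)
  m <- mtt_model(0.6225, 0.4502, 5, r = 6, R = 0)
  d <- simulate_mtt(m, 2000)
  fit <- fit_mtt(d, 6, 0)
  expect_lt(abs(coef(fit)["alpha1"] - 0.6225), 0.08)
  expect_lt(abs(coef(fit)["alpha2"] - 0.4502), 0.08)
  expect_lt(abs(coef(fit)["lambda"] - 5), 0.6)
  expect_true(fit$converged)
})

test_that("likelihood-ratio statistic is non-negative by nesting", {
  set.seed(6)
  m <- mtt_model(0.6225, 0.4502, 5, r = 6, R = 0)
  d <- simulate_mtt(m, 500)
  d$z1 <- runif(500, -10, 1)
  res <- test_covariates_lr(d, 6, 0)
  expect_gte(res$statistic, -1e-6)
  expect_equal(res$critical_value, qchisq(0.95, 2))
  expect_equal(res$statistic,
               2 * (res$loglik_full - res$loglik_null))
})

test_that("null statistics track their reference distributions", {
  # Tn(1) under a single-regime null vs standard normal (KS)
  set.seed(7)
  reps <- 500
  ctrl <- tvmt_control(extra_starts = 1)
  des <- sim_design("T11")
  t1 <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    d <- simulate_design(des, 1000)
    r <- as.integer(median(d$x))
    t1[i] <- suppressWarnings(
      test_piecewise(fit_cls(d, r, 0, ctrl))$statistic)
  }
  expect_gt(stats::ks.test(t1, "pnorm")$p.value, 0.01)

  # Tn(3) under the constant-coefficient null vs chi-square(2q) (KS)
  set.seed(8)
  des3 <- sim_design("T41")
  t3 <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    d <- simulate_design(des3, 1000)
    t3[i] <- suppressWarnings(
      test_covariates_lr(d, 6, 0, control = ctrl)$statistic)
  }
  expect_gt(stats::ks.test(pmax(t3, 0), "pchisq", df = 2)$p.value, 0.01)
})
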