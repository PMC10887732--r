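test_that("CLS criterion is exact arithmetic over the transitions", {
  # constant series reproduced exactly: phi = 0.5, x = 4, lambda = 2
  d <- toy_series(rep(4L, 6), rep(0, 6))
  th <- c(0, 0, 0, 0, 2)  # beta1 = beta2 = (0, 0) -> phi = 0.5
  expect_equal(cls_objective(th, d, r = 10, R = 0), 0)
  expect_equal(model_rms(d, tvmt_model(c(0, 0), c(0, 0), 2, 10)), 0)

  # three-point series, hand-summed squares
  d3 <- toy_series(c(2L, 5L, 1L), c(0.2, -0.1, 0.4))
  b1 <- c(0.1, 0.3); b2 <- c(-0.5, -0.6); lam <- 1.5
  g2 <- plogis(sum(c(1, -0.1) * b1)) * 2 + lam   # x_prev = 2 <= r
  g3 <- plogis(sum(c(1, 0.4) * b2)) * 5 + lam    # x_prev = 5 > r
  hand <- (5 - g2)^2 + (1 - g3)^2
  expect_equal(cls_objective(c(b1, b2, lam), d3, r = 3, R = 0), hand)

  # non-negativity at arbitrary parameters
  set.seed(1)
  for (i in 1:5) {
    th <- c(runif(4, -2, 2), runif(1, 0.1, 8))
    expect_gte(cls_objective(th, d3, r = 3, R = 0), 0)
  }
})

test_that("analytic CLS gradient matches central finite differences", {
  set.seed(2)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 300, list(cov_iid_normal()))
  sm <- tvmttinar:::series_matrices(d)
  th <- c(0.2, 0.1, -0.3, -0.4, 4.5)
  g <- tvmttinar:::cls_grad_raw(th, sm$x, sm$Z, sm$q, 6, 0)
  fd <- fd_grad(function(p) cls_objective(p, d, 6, 0), th, h = 1e-5)
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1)), 1e-6)
})

test_that("CLS minimizer dominates the truth and a local grid", {
  set.seed(3)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 600, list(cov_iid_normal()))
  fit <- fit_cls(d, 6)
  q_hat <- fit$objective
  expect_lte(q_hat, cls_objective(c(m$beta1, m$beta2, m$lambda), d, 6, 0))
  # coarse scan over a 2-parameter slice around the optimum
  th <- unname(coef(fit))
  for (a in seq(-0.2, 0.2, by = 0.1)) {
    for (b in seq(-0.2, 0.2, by = 0.1)) {
      th2 <- th; th2[1] <- th2[1] + a; th2[5] <- th2[5] + b
      expect_gte(cls_objective(th2, d, 6, 0), q_hat - 1e-8)
    }
  }
})

test_that("CML log-likelihood equals the brute-force transition sum", {
  # single transition
  d1 <- toy_series(c(3L, 2L), c(0.1, -0.2))
  b1 <- c(0.1, 0.3); b2 <- c(-0.5, -0.6); lam <- 1.2
  m <- tvmt_model(b1, b2, lam, r = 6)
  expect_equal(cml_loglik(c(b1, b2, lam), d1, 6, 0),
               log(transition_pmf(3, 2, c(1, -0.2), m)),
               tolerance = 1e-12)
  # five-point series crossing both regimes, oracle convolution
  d5 <- toy_series(c(2L, 8L, 9L, 3L, 0L), c(0.5, -0.3, 0.2, 0, 1))
  ll <- 0
  for (t in 2:5) {
    z <- c(1, d5$z1[t]); xp <- d5$x[t - 1]
    if (xp <= 6) {
      ll <- ll + log(oracle_transition(xp, d5$x[t],
                                       plogis(sum(z * b1)), lam, "binomial"))
    } else {
      ll <- ll + log(oracle_transition(xp, d5$x[t],
                                       plogis(sum(z * b2)), lam, "nbinom"))
    }
  }
  expect_equal(cml_loglik(c(b1, b2, lam), d5, 6, 0), ll, tolerance = 1e-10)
  expect_true(is.finite(cml_loglik(c(b1, b2, lam), d5, 6, 0)))
})

test_that("analytic CML score matches finite differences of the likelihood", {
  set.seed(4)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 300, list(cov_iid_normal()))
  sm <- tvmttinar:::series_matrices(d)
  th <- c(0.15, 0.2, -0.4, -0.5, 4.8)
  vg <- tvmttinar:::cml_value_grad_raw(th, sm$x, sm$Z, sm$q, 6, 0)
  fd <- fd_grad(function(p) cml_loglik(p, d, 6, 0), th, h = 1e-5)
  expect_lt(max(abs(vg$grad - fd) / pmax(abs(fd), 1)), 1e-6)
})

test_that("CML dominates CLS in likelihood and the fits are coherent", {
  set.seed(5)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 800, list(cov_iid_normal()))
  f_cls <- fit_cls(d, 6)
  f_cml <- fit_cml(d, 6, cls_start = f_cls)
  expect_gte(f_cml$objective,
             cml_loglik(unname(coef(f_cls)), d, 6, 0) - 1e-6)
  expect_gt(unname(coef(f_cml)["lambda"]), 0)
  expect_true(all(is.finite(f_cml$se)))
})

test_that("Q and L are invariant under covariate rescaling", {
  set.seed(6)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 300, list(cov_iid_normal()))
  th <- c(0.1, 0.3, -0.5, -0.6, 5)
  c0 <- 3.7
  d2 <- d; d2$z1 <- d2$z1 * c0
  th2 <- c(0.1, 0.3 / c0, -0.5, -0.6 / c0, 5)
  expect_equal(cls_objective(th, d, 6, 0), cls_objective(th2, d2, 6, 0),
               tolerance = 1e-10)
  expect_equal(cml_loglik(th, d, 6, 0), cml_loglik(th2, d2, 6, 0),
               tolerance = 1e-10)
})

test_that("sandwich pieces are symmetric PSD and factor in the
           homoskedastic case", {
  set.seed(7)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 500, list(cov_iid_normal()))
  fit <- fit_cls(d, 6)
  sw <- fit$sandwich
  expect_equal(sw$V, t(sw$V))
  expect_equal(sw$W, t(sw$W))
  expect_true(all(eigen(sw$V, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(sw$W, symmetric = TRUE)$values > -1e-10))
  expect_true(all(eigen(sw$Sigma, symmetric = TRUE)$values > -1e-10))

  # constant residuals: x = 4 everywhere, g = 3 => U_t^2 = 1, so W = 1 * V
  # (computed from the score pieces directly; a single active regime makes
  # V itself singular, which sandwich_covariance would rightly refuse)
  dc <- toy_series(rep(4L, 8), rep(0, 8))
  smc <- tvmttinar:::series_matrices(dc)
  parts <- tvmttinar:::cls_score_parts(c(0, 0, 0, 0, 1), smc$x, smc$Z,
                                       smc$q, 10, 0)
  expect_equal(unique(parts$U^2), 1)
  nC <- length(parts$U)
  expect_equal(crossprod(parts$D * parts$U) / nC,
               crossprod(parts$D) / nC, tolerance = 1e-12)
})

test_that("CLS sandwich intervals achieve near-nominal coverage", {
  set.seed(8)
  des <- sim_design("A1")
  theta0 <- des$theta_true
  reps <- 500
  cover <- matrix(NA, reps, length(theta0))
  ctrl <- tvmt_control(extra_starts = 1)
  for (i in seq_len(reps)) {
    d <- simulate_design(des, 1000)
    fit <- suppressWarnings(fit_cls(d, 6, 0, ctrl))
    cover[i, ] <- abs(coef(fit) - theta0) <= qnorm(0.975) * fit$se
  }
  cov_rate <- colMeans(cover)
  expect_true(all(cov_rate >= 0.92 & cov_rate <= 0.98))
})

test_that("threshold candidates span the empirical deciles", {
  x <- rep(4:12, each = 10)
  expect_identical(threshold_candidates(x), 4:12)
  d <- tibble::tibble(t = seq_along(x), x = x)
  expect_error(threshold_candidates(integer(0)))
})

test_that("grid search recovers a strongly separated threshold", {
  # strong growth below the threshold, sharp decay above it, so the path
  # oscillates across r and the regimes are wildly different
  set.seed(9)
  m <- tvmt_model(c(qlogis(0.9), 0), c(qlogis(0.05), 0), lambda = 1,
                  r = 6, R = 0)
  d <- simulate_tvmt(m, 2000, list(cov_iid_normal()))
  fit <- suppressWarnings(
    fit_threshold(d, 0, "cls", tvmt_control(extra_starts = 1)))
  expect_identical(fit$r, 6L)
  expect_s3_class(fit$profile, "tbl_df")
  expect_identical(fit$profile$r, threshold_candidates(d$x))
})

test_that("fit accessors and broom methods are consistent", {
  set.seed(10)
  m <- tvmt_model(c(0.1, 0.3), c(-0.5, -0.6), lambda = 5, r = 6)
  d <- simulate_tvmt(m, 400, list(cov_iid_normal()))
  fit <- fit_cml(d, 6)
  td <- tidy(fit)
  expect_identical(td$term, tvmttinar:::theta_names(1))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$objective)
  expect_equal(gl$BIC - gl$AIC, 5 * (log(fit$n_used) - 2))
})
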