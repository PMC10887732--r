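#' Monte Carlo study of estimator bias and mean squared error
#'
#' Repeatedly simulates a TVMTTINAR(1) design, fits it by the chosen method
#' (at the true threshold, or with the two-step grid search when
#' `r_known = FALSE`), and summarizes per-parameter bias and MSE together
#' with their Monte Carlo standard errors. Covariate paths are regenerated
#' independently for every replication. Fully deterministic given `seed`.
#'
#' @param design Design name (see [sim_design()]) or `sim_design` object;
#'   must be one of the TVMTTINAR designs (`A1`–`B3`, `T31`, ...).
#' @param n Series length per replication.
#' @param reps Number of replications.
#' @param method `"cml"` or `"cls"`.
#' @param r_known Fit at the design threshold (`TRUE`) or estimate it by
#'   grid search (`FALSE`).
#' @param seed Integer seed (set once before the loop).
#' @param control A [tvmt_control()]; the default trims the randomized
#'   extra starts to one for desk-scale runtimes.
#' @param burn_in Simulation burn-in.
#' @return A tibble with one row per parameter (`term`, `true`, `bias`,
#'   `mse`, `bias_mc_se`, `mse_mc_se`), including a row for `r` when it is
#'   estimated. Attributes: `reps`, `failures`, `r_frequency` (proportion
#'   of replications recovering the true threshold; `NA` when `r_known`).
#' @export
mc_estimation <- function(design, n, reps, method = c("cml", "cls"),
                          r_known = TRUE, seed = NULL,
                          control = tvmt_control(extra_starts = 1),
                          burn_in = 500) {
  method <- match.arg(method)
  if (is.character(design)) design <- sim_design(design)
  if (design$kind != "tvmt") {
    abort("bias/MSE studies are defined for the TVMTTINAR designs.")
  }
  if (reps < 1) abort("`reps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  p <- length(design$theta_true)
  est <- matrix(NA_real_, reps, p)
  r_hat <- rep(NA_integer_, reps)
  failures <- 0L
  for (i in seq_len(reps)) {
    fit <- tryCatch(suppressWarnings({
      d <- simulate_design(design, n, burn_in)
      if (r_known) {
        if (method == "cml") fit_cml(d, design$r_true, design$R_fit, control)
        else fit_cls(d, design$r_true, design$R_fit, control)
      } else {
        fit_threshold(d, design$R_fit, method, control)
      }
    }), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    est[i, ] <- unname(fit$coefficients)
    r_hat[i] <- fit$r
  }
  ok <- !is.na(est[, 1])
  if (!any(ok)) abort("every replication failed.")
  err <- sweep(est[ok, , drop = FALSE], 2, design$theta_true)
  out <- tibble(
    term = theta_names(length(design$model$beta1) - 1),
    true = design$theta_true,
    bias = colMeans(err),
    mse = colMeans(err^2),
    bias_mc_se = apply(err, 2, sd) / sqrt(sum(ok)),
    mse_mc_se = apply(err^2, 2, sd) / sqrt(sum(ok))
  )
  if (!r_known) {
    rerr <- r_hat[ok] - design$r_true
    out <- dplyr::bind_rows(out, tibble(
      term = "r", true = design$r_true,
      bias = mean(rerr), mse = mean(rerr^2),
      bias_mc_se = sd(rerr) / sqrt(sum(ok)),
      mse_mc_se = sd(rerr^2) / sqrt(sum(ok))))
  }
  attr(out, "reps") <- reps
  attr(out, "failures") <- failures
  attr(out, "r_frequency") <-
    if (r_known) NA_real_ else mean(r_hat[ok] == design$r_true)
  attr(out, "seed") <- seed
  out
}

#' Monte Carlo size / power of the hypothesis tests
#'
#' Repeatedly simulates a design, fits the time-varying threshold model,
#' applies the chosen statistic, and reports the empirical rejection rate
#' at the nominal level. `stat = "T1"` is the one-sided Wald test of the
#' piecewise structure from a CLS fit; `"T2"` the Wald test of explanatory
#' variables from a CLS fit; `"T3"` the likelihood-ratio test against the
#' constant-coefficient MTTINAR(1) null. The threshold supplied to the fits
#' is the design's true value where the generating process has one, and
#' the per-replication sample median otherwise.
#'
#' @inheritParams mc_estimation
#' @param stat `"T1"`, `"T2"` or `"T3"`.
#' @param level Nominal size.
#' @return One-row tibble: `design`, `stat`, `n`, `reps`, `rejections`,
#'   `rate`, `mc_se` (binomial standard error of the rate), `failures`.
#' @export
mc_test <- function(design, n, reps, stat = c("T1", "T2", "T3"),
                    level = 0.05, seed = NULL,
                    control = tvmt_control(extra_starts = 1),
                    burn_in = 500) {
  stat <- match.arg(stat)
  if (is.character(design)) design <- sim_design(design)
  if (reps < 1) abort("`reps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  reject <- rep(NA, reps)
  failures <- 0L
  for (i in seq_len(reps)) {
    res <- tryCatch(suppressWarnings({
      d <- simulate_design(design, n, burn_in)
      r <- design_fit_threshold(design, d)
      if (stat == "T1") {
        test_piecewise(fit_cls(d, r, design$R_fit, control), level)
      } else if (stat == "T2") {
        test_covariates_wald(fit_cls(d, r, design$R_fit, control), level)
      } else {
        test_covariates_lr(d, r, design$R_fit, level, control)
      }
    }), error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    reject[i] <- res$reject
  }
  ok <- !is.na(reject)
  if (!any(ok)) abort("every replication failed.")
  rate <- mean(reject[ok])
  tibble(design = design$name, stat = stat, n = n, reps = sum(ok),
         rejections = sum(reject[ok]), rate = rate,
         mc_se = sqrt(rate * (1 - rate) / sum(ok)),
         failures = failures)
}

#' Monte Carlo frequency of correct threshold recovery
#'
#' Repeatedly simulates a TVMTTINAR(1) design and runs the two-step grid
#' search [fit_threshold()], reporting how often the estimated integer
#' threshold equals the design value.
#'
#' @inheritParams mc_estimation
#' @return One-row tibble: `design`, `method`, `n`, `reps`, `frequency`,
#'   `mc_se`, `failures`.
#' @export
mc_threshold <- function(design, n, reps, method = c("cml", "cls"),
                         seed = NULL,
                         control = tvmt_control(extra_starts = 1),
                         burn_in = 500) {
  method <- match.arg(method)
  if (is.character(design)) design <- sim_design(design)
  if (design$kind != "tvmt") {
    abort("threshold recovery is defined for the TVMTTINAR designs.")
  }
  if (reps < 1) abort("`reps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  hit <- rep(NA, reps)
  failures <- 0L
  for (i in seq_len(reps)) {
    fit <- tryCatch(suppressWarnings({
      d <- simulate_design(design, n, burn_in)
      fit_threshold(d, design$R_fit, method, control)
    }), error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    hit[i] <- fit$r == design$r_true
  }
  ok <- !is.na(hit)
  if (!any(ok)) abort("every replication failed.")
  freq <- mean(hit[ok])
  tibble(design = design$name, method = toupper(method), n = n,
         reps = sum(ok), frequency = freq,
         mc_se = sqrt(freq * (1 - freq) / sum(ok)),
         failures = failures)
}
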