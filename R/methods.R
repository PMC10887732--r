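#' @export
print.tvmt_fit <- function(x, ...) {
  cat(sprintf("TVMTTINAR(1) fit (%s), r = %d, R = %d, n = %d\n",
              x$method, x$r, x$R, x$n_used))
  print(cbind(estimate = x$coefficients, std.error = x$se))
  lab <- if (x$method == "CML") "logLik" else "Q"
  cat(lab, "=", format(x$objective),
      if (!x$converged) " (optimizer did not report convergence)", "\n")
  invisible(x)
}

#' @export
coef.tvmt_fit <- function(object, ...) object$coefficients

#' @export
vcov.tvmt_fit <- function(object, ...) object$vcov

#' @export
logLik.tvmt_fit <- function(object, ...) {
  if (object$method != "CML") {
    abort("log-likelihood only available for CML fits.")
  }
  structure(object$objective, df = 2 * object$q + 3,
            nobs = object$n_used, class = "logLik")
}

#' Tidy a TVMTTINAR(1) fit
#'
#' @param x A `tvmt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.tvmt_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' One-row summary of a TVMTTINAR(1) fit
#'
#' @inheritParams tidy.tvmt_fit
#' @return Tibble with method, threshold, orientation, criterion value,
#'   AIC/BIC (CML), sample size and convergence flag.
#' @export
glance.tvmt_fit <- function(x, ...) {
  k <- 2 * x$q + 3
  ll <- if (x$method == "CML") x$objective else NA_real_
  ic <- if (is.na(ll)) list(aic = NA_real_, bic = NA_real_)
        else info_criteria(ll, k, x$n_used)
  tibble(method = x$method, r = x$r, R = x$R,
         objective = x$objective, logLik = ll,
         AIC = ic$aic, BIC = ic$bic,
         n = x$n_used, converged = x$converged)
}

#' Plot methods
#'
#' `autoplot.tvmt_fit()` shows Pearson residuals over time with their
#' sample mean; `plot_threshold_profile()` draws the grid-search objective
#' over candidate thresholds from a [fit_threshold()] result;
#' `plot_series()` draws a simulated or observed count path.
#'
#' @param object A `tvmt_fit`.
#' @param data Series tibble (defaults to the data stored in the fit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tvmt_fit <- function(object, data = object$data, ...) {
  pr <- residuals(object, data)
  df <- tibble(t = seq_along(pr), residual = pr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = mean(pr), colour = "red") +
    ggplot2::labs(x = "t", y = "Pearson residual",
                  title = sprintf("%s fit, r = %d", object$method,
                                  object$r))
}

#' @rdname autoplot.tvmt_fit
#' @param fit A `tvmt_fit` from [fit_threshold()].
#' @export
plot_threshold_profile <- function(fit, ...) {
  if (is.null(fit$profile)) abort("fit has no threshold profile.")
  lab <- if (fit$method == "CML") "log-likelihood" else "Q (CLS criterion)"
  ggplot2::ggplot(fit$profile,
                  ggplot2::aes(x = .data$r, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = fit$r, linetype = 2, colour = "red") +
    ggplot2::labs(x = "candidate threshold r", y = lab)
}

#' @rdname autoplot.tvmt_fit
#' @export
plot_series <- function(data, ...) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "t", y = "count")
}
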