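#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted logistic NTCP model
#'
#' One row per term with the log-odds estimate, Wald standard error and
#' p-value, the odds ratio, and its Wald confidence interval at the fit's
#' confidence level.
#'
#' @param x A `pce_logistic` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pce_logistic
#' @export
tidy.pce_logistic <- function(x, ...) {
  cf <- c("(Intercept)" = x$model$intercept, x$model$coefficients)
  se <- sqrt(diag(x$model$covariance))
  z <- cf / se
  q <- qnorm(1 - (1 - x$level) / 2)
  tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    odds.ratio = exp(unname(cf)),
    conf.low = exp(unname(cf - q * se)),
    conf.high = exp(unname(cf + q * se))
  )
}

#' @rdname tidy.pce_logistic
#' @method glance pce_logistic
#' @export
glance.pce_logistic <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    deviance = x$deviance,
    null.deviance = x$null_deviance,
    nobs = x$n_patients,
    converged = x$converged,
    n.features = length(x$model$coefficients)
  )
}

#' Tidy a fitted LKB model
#'
#' @param x An `lkb_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (n, m, TD50) with the estimate
#'   and the log-scale gradient at the optimum (a near-zero gradient on a
#'   parameter held flat by the data, e.g. n under uniform dose, flags
#'   unidentifiability); `glance()`: fit summary.
#' @method tidy lkb_fit
#' @export
tidy.lkb_fit <- function(x, ...) {
  est <- c(n = x$params$n, m = x$params$m, td50 = x$params$td50)
  grad <- rep(NA_real_, 3)
  names(grad) <- c("n", "m", "td50")
  grad[names(x$gradient)] <- x$gradient
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    fixed = c(!is.na(x$fixed_n), FALSE, FALSE),
    gradient = unname(grad)
  )
}

#' @rdname tidy.lkb_fit
#' @method glance lkb_fit
#' @export
glance.lkb_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    nobs = x$n_patients,
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Tidy a Hosmer-Lemeshow test
#'
#' @param x An `hl_test`.
#' @param ... Unused.
#' @return `tidy()`: the per-group calibration bins (`mean_predicted`,
#'   `observed_rate`, `n`); `glance()`: the statistic, df and p-value.
#' @method tidy hl_test
#' @export
tidy.hl_test <- function(x, ...) {
  x$bins
}

#' @rdname tidy.hl_test
#' @method glance hl_test
#' @export
glance.hl_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi_squared,
    p.value = x$p_value,
    df = x$df,
    groups = x$groups
  )
}
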