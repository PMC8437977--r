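#' LKB dose-response parameters
#'
#' The Lyman-Kutcher-Burman model describes the complication probability of
#' an organ as a probit function of the generalised equivalent uniform dose:
#' NTCP = Phi((gEUD - TD50) / (m * TD50)). `n` controls the volume effect
#' (n near 1: large volume effect, mean-dose-like behaviour; n near 0: the
#' hottest subvolume dominates), `m` the steepness of the dose-response
#' curve, and `TD50` the uniform whole-organ dose giving 50% complication
#' probability. `n = 1` is the mean-heart-dose (MHD) based reduction, where
#' the dose metric is simply the mean dose.
#'
#' @param n Volume-effect exponent, > 0.
#' @param m Slope parameter, > 0.
#' @param td50 Dose (Gy) at 50% complication probability, > 0.
#' @return An object of class `lkb_params`.
#' @examples
#' lkb_params(n = 1, m = 0.75, td50 = 34.3)
#' @export
lkb_params <- function(n, m, td50) {
  vals <- c(n = n, m = m, td50 = td50)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_domain("LKB parameters n, m, td50 must all be strictly positive")
  }
  structure(list(n = n, m = m, td50 = td50), class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("<lkb_params> n = %.4g, m = %.4g, TD50 = %.4g Gy\n", x$n, x$m, x$td50))
  invisible(x)
}

#' Logistic NTCP model
#'
#' An intercept plus named per-feature log-odds coefficients; the
#' complication probability of a patient is the inverse logit of the linear
#' predictor. The odds ratio of a feature is `exp(coefficient)`.
#'
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Named numeric vector of log-odds coefficients.
#' @param covariance Optional coefficient covariance matrix (intercept
#'   first), used for Wald confidence intervals.
#' @return An object of class `logistic_model`.
#' @examples
#' # any-grade pericardial effusion risk per Gy of mean heart dose
#' logistic_model(-2.513, c(mhd = 0.073))
#' @export
logistic_model <- function(intercept, coefficients, covariance = NULL) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    abort_domain("intercept must be a finite scalar")
  }
  if (length(coefficients) == 0L || is.null(names(coefficients)) ||
    any(!nzchar(names(coefficients)))) {
    abort_domain("coefficients must be a named numeric vector")
  }
  structure(
    list(
      intercept = intercept,
      coefficients = coefficients,
      covariance = covariance
    ),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf(
    "<logistic_model> intercept %.4g; %s\n", x$intercept,
    paste(sprintf("%s = %.4g (OR %.3f)", names(x$coefficients), x$coefficients,
      exp(x$coefficients)), collapse = ", ")
  ))
  invisible(x)
}

#' Odds ratios of a logistic model
#'
#' @param model A [logistic_model()].
#' @return Named vector `exp(coefficients)`.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  exp(model$coefficients)
}

#' Generalised equivalent uniform dose
#'
#' gEUD is the power mean of the dose distribution with exponent 1/n:
#' `(sum_i v_i * D_i^(1/n))^n` over bins with fractional volume `v_i` at
#' dose `D_i`. It is the uniform dose with the same modelled effect as the
#' heterogeneous distribution: at n = 1 it equals the mean dose, and as
#' n tends to 0 it approaches the maximum dose. Zero-dose bins contribute
#' nothing to the power sum.
#'
#' @param x A [dvh()].
#' @param n Volume-effect exponent, > 0. Vectorised.
#' @return gEUD in Gy.
#' @examples
#' d <- dvh(c(10, 40), c(0.5, 0.5), structure = "heart")
#' geud(d, n = 0.5) # sqrt(0.5*10^2 + 0.5*40^2)
#' geud(d, n = 1) # mean dose
#' @export
geud <- function(x, n) {
  check_dvh(x)
  if (any(!is.finite(n)) || any(n <= 0)) {
    abort_domain("gEUD exponent n must be strictly positive")
  }
  pos <- x$dose_gy > 0 & x$volume_fraction > 0
  if (!any(pos)) return(rep(0, length(n)))
  d <- x$dose_gy[pos]
  v <- x$volume_fraction[pos]
  logd <- log(d)
  vapply(n, function(nn) {
    # computed on the log scale for numerical stability at small n
    a <- 1 / nn
    mx <- max(logd)
    exp(mx + nn * log(sum(v * exp(a * (logd - mx)))))
  }, numeric(1))
}

#' Probit (LKB-form) NTCP
#'
#' NTCP = Phi((D - TD50) / (m * TD50)), with Phi the standard normal
#' cumulative distribution. `D` is gEUD for the full LKB model or the mean
#' heart dose for the n = 1 reduction.
#'
#' @param dose_metric Dose metric in Gy (gEUD or mean dose). Vectorised.
#' @param params An [lkb_params()].
#' @return Complication probability in (0, 1).
#' @examples
#' probit_ntcp(30, lkb_params(1, 0.75, 34.3))
#' @export
probit_ntcp <- function(dose_metric, params) {
  stopifnot(inherits(params, "lkb_params"))
  if (any(dose_metric < 0)) abort_domain("dose metric must be non-negative")
  pnorm((dose_metric - params$td50) / (params$m * params$td50))
}

#' Logistic NTCP
#'
#' Inverse logit of `intercept + sum(coefficient * feature)`.
#'
#' @param features A named numeric vector, a named list, or a data frame
#'   with one row per patient; must contain every model feature.
#' @param model A [logistic_model()].
#' @return Complication probability in (0, 1), one per patient.
#' @examples
#' m <- logistic_model(-2.513, c(mhd = 0.073))
#' logistic_ntcp(c(mhd = 30), m)
#' @export
logistic_ntcp <- function(features, model) {
  stopifnot(inherits(model, "logistic_model"))
  nm <- names(model$coefficients)
  if (is.data.frame(features)) {
    missing <- setdiff(nm, names(features))
    if (length(missing) > 0L) {
      abort_contract(sprintf("missing model feature(s): %s", paste(missing, collapse = ", ")))
    }
    eta <- model$intercept +
      as.numeric(as.matrix(features[nm]) %*% model$coefficients)
  } else {
    features <- unlist(features)
    missing <- setdiff(nm, names(features))
    if (length(missing) > 0L) {
      abort_contract(sprintf("missing model feature(s): %s", paste(missing, collapse = ", ")))
    }
    eta <- model$intercept + sum(model$coefficients * features[nm])
  }
  plogis(eta)
}

#' Tolerance dose at a target complication probability
#'
#' Inverts a dose-response model: the dose at which the modelled NTCP
#' equals `x`. For the probit models the closed form is
#' `TD_x = TD50 * (1 + m * qnorm(x))`; for a logistic model it is
#' `(logit(x) - intercept - offset) / dose coefficient`, where the offset
#' collects the non-dose covariates at a declared profile. When the
#' solution is not a positive dose the tolerance dose is not achieved:
#' the model never drops to probability `x` on the physical dose axis, and
#' `NA` is returned (rendered as a dash in tables).
#'
#' @param model An [lkb_params()] or [logistic_model()].
#' @param x Target probability in (0, 1). Vectorised.
#' @param dose_feature For logistic models with more than one coefficient,
#'   the name of the dose feature to solve for.
#' @param profile Named values for the remaining covariates of a
#'   multivariable logistic model. Required when such covariates exist: no
#'   default patient profile is assumed.
#' @return Dose in Gy, `NA` where the tolerance dose is not achieved.
#' @examples
#' invert_td(lkb_params(1, 0.75, 34.3), 0.5) # TD50 itself
#' invert_td(logistic_model(-2.513, c(mhd = 0.073)), 0.25)
#' @export
invert_td <- function(model, x, dose_feature = NULL, profile = NULL) {
  if (any(x <= 0 | x >= 1)) abort_domain("target probability must be in (0, 1)")
  if (inherits(model, "lkb_params")) {
    d <- model$td50 * (1 + model$m * qnorm(x))
  } else if (inherits(model, "logistic_model")) {
    coefs <- model$coefficients
    if (length(coefs) == 1L) {
      dose_feature <- names(coefs)
      offset <- 0
    } else {
      if (is.null(dose_feature) || is.null(profile)) {
        abort_contract(paste(
          "multivariable logistic model: declare 'dose_feature' and a",
          "covariate 'profile' for the remaining features"
        ))
      }
      others <- setdiff(names(coefs), dose_feature)
      if (!all(others %in% names(profile))) {
        abort_contract("profile must value every non-dose covariate")
      }
      offset <- sum(coefs[others] * unlist(profile)[others])
    }
    d <- (qlogis(x) - model$intercept - offset) / coefs[[dose_feature]]
  } else {
    abort_contract("model must be lkb_params or logistic_model")
  }
  d[d <= 0] <- NA_real_
  unname(d)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)` for observed values
#' `y` and fitted values `f`. Used to quantify agreement between the
#' MHD-based and LKB NTCP curves under linear regression.
#'
#' @param observed Observed values, length >= 2, non-constant.
#' @param fitted Fitted values, same length.
#' @return R-squared (at most 1; can be negative for fits worse than the
#'   mean).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) abort_contract("lengths must match")
  if (length(observed) < 2L) abort_contract("need at least two points")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) abort_domain("observed values are constant")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Evaluate an NTCP model on a cohort
#'
#' Computes the per-patient complication probability. Probit models with
#' n = 1 use the `mhd` column; other volume-effect exponents require the
#' `dvh` list-column, from which the gEUD at the model's `n` is computed.
#' Logistic models read their features from cohort columns.
#'
#' @param model An [lkb_params()] or [logistic_model()].
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @return Numeric vector of probabilities, one per patient.
#' @export
predict_ntcp <- function(model, cohort) {
  if (inherits(model, "logistic_model")) {
    return(logistic_ntcp(cohort, model))
  }
  stopifnot(inherits(model, "lkb_params"))
  dose <- cohort_dose_metric(cohort, model$n)
  probit_ntcp(dose, model)
}

cohort_dose_metric <- function(cohort, n) {
  if (abs(n - 1) < 1e-12 && "mhd" %in% names(cohort)) {
    return(cohort$mhd)
  }
  if (!"dvh" %in% names(cohort)) {
    abort_contract("gEUD at n != 1 requires a 'dvh' list-column in the cohort")
  }
  vapply(cohort$dvh, geud, numeric(1), n = n)
}

#' Read or write NTCP model parameter files
#'
#' Models are stored as small JSON documents carrying the model type and
#' its parameters (and covariate names for logistic models), so a fitted
#' model can be re-evaluated reproducibly.
#'
#' @param model An [lkb_params()] or [logistic_model()].
#' @param path File path.
#' @return `read_model()` returns the model object; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  doc <- if (inherits(model, "lkb_params")) {
    list(type = "lkb", n = model$n, m = model$m, td50 = model$td50)
  } else if (inherits(model, "logistic_model")) {
    list(
      type = "logistic",
      intercept = model$intercept,
      features = names(model$coefficients),
      coefficients = unname(model$coefficients)
    )
  } else {
    abort_contract("model must be lkb_params or logistic_model")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "lkb")) {
    lkb_params(doc$n, doc$m, doc$td50)
  } else if (identical(doc$type, "logistic")) {
    logistic_model(doc$intercept, setNames(doc$coefficients, doc$features))
  } else {
    abort_config(sprintf("unknown model type '%s'", doc$type))
  }
}
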