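#' Binomial log-likelihood of predicted probabilities
#'
#' `sum(y * log(p) + (1 - y) * log(1 - p))` in nats, with probabilities
#' clipped to `[clip, 1 - clip]` so the likelihood stays finite under
#' extreme parameters.
#'
#' @param predictions Predicted probabilities.
#' @param outcomes Binary outcomes (0/1), same length.
#' @param clip Clipping bound, default `1e-12`.
#' @return Log-likelihood in nats (non-positive).
#' @export
binary_log_likelihood <- function(predictions, outcomes, clip = 1e-12) {
  if (length(predictions) != length(outcomes)) {
    abort_contract("predictions and outcomes must have equal length")
  }
  p <- pmin(pmax(predictions, clip), 1 - clip)
  sum(outcomes * log(p) + (1 - outcomes) * log1p(-p))
}

# log-likelihood of an (m, td50) probit model given a fixed dose-metric
# vector; the workhorse of the LKB fit
probit_ll <- function(dose, m, td50, y) {
  binary_log_likelihood(pnorm((dose - td50) / (m * td50)), y)
}

#' Maximum-likelihood fit of the LKB model
#'
#' Estimates the LKB parameters (n, m, TD50) — or (m, TD50) with the
#' volume-effect exponent fixed, e.g. `fix_n = 1` for the mean-heart-dose
#' reduction — by maximising the binomial likelihood of the probit
#' dose-response over the cohort. The optimiser is a coarse-grid
#' multi-start followed by gradient ascent on log-parameters (so the box
#' positivity constraints hold by construction) with a backtracking line
#' search; convergence is declared when the projected-gradient max-norm
#' falls below `tol`.
#'
#' @param cohort Cohort tibble with outcome columns and either a `dvh`
#'   list-column (free-n fit) or an `mhd` column (n = 1 fit).
#' @param outcome `"any"` (any-grade PCE) or `"symptomatic"`.
#' @param fix_n Optional fixed volume-effect exponent; `fix_n = 1` fits the
#'   MHD-based probit model.
#' @param bounds Named list of length-2 ranges for `n`, `m` and `td50`
#'   (Gy). Defaults bracket published pericardium estimates.
#' @param tol Convergence tolerance on the projected-gradient max-norm.
#' @param max_iter Maximum gradient-ascent iterations per start.
#' @param n_starts Number of best grid points used as starts.
#' @return An object of class `lkb_fit`: `params` ([lkb_params()]),
#'   `log_likelihood`, `converged`, `iterations`, `gradient` (on the
#'   log-parameter scale; a near-zero `n` component flags an
#'   unidentifiable volume effect, e.g. uniform-dose cohorts),
#'   `n_patients`, `fixed_n`.
#' @export
fit_lkb <- function(cohort, outcome = c("any", "symptomatic"), fix_n = NULL,
                    bounds = list(n = c(0.05, 2), m = c(0.05, 2), td50 = c(5, 120)),
                    tol = 1e-6, max_iter = 500L, n_starts = 3L) {
  outcome <- match.arg(outcome)
  y <- check_fit_feasible(outcome_vector(cohort, outcome))
  free_n <- is.null(fix_n)
  if (!free_n && (!is.finite(fix_n) || fix_n <= 0)) {
    abort_domain("fix_n must be strictly positive")
  }

  # gEUD depends only on n; evaluate it for the whole cohort at once by
  # stacking all DVH bins and reducing per patient, and cache per unique n
  # so line searches at fixed n are cheap
  stacked <- if ("dvh" %in% names(cohort)) stack_dvhs(cohort$dvh) else NULL
  geud_cache <- new.env(parent = emptyenv())
  dose_at <- function(n) {
    key <- sprintf("%.17g", n)
    got <- geud_cache[[key]]
    if (is.null(got)) {
      got <- if (abs(n - 1) < 1e-12 && "mhd" %in% names(cohort)) {
        cohort$mhd
      } else if (!is.null(stacked)) {
        stacked_geud(stacked, n)
      } else {
        cohort_dose_metric(cohort, n)
      }
      geud_cache[[key]] <- got
    }
    got
  }

  ll_nat <- function(n, m, td50) probit_ll(dose_at(n), m, td50, y)

  lo <- log(c(bounds$n[1], bounds$m[1], bounds$td50[1]))
  hi <- log(c(bounds$n[2], bounds$m[2], bounds$td50[2]))
  if (free_n) {
    f <- function(th) ll_nat(exp(th[1]), exp(th[2]), exp(th[3]))
    box_lo <- lo
    box_hi <- hi
    grid <- make_grid(bounds, n_n = 9L, n_m = 9L, n_t = 12L)
  } else {
    f <- function(th) ll_nat(fix_n, exp(th[1]), exp(th[2]))
    box_lo <- lo[2:3]
    box_hi <- hi[2:3]
    grid <- make_grid(bounds, n_n = 1L, n_m = 11L, n_t = 14L, fix_n = fix_n)
  }
  grid$ll <- purrr::pmap_dbl(grid, function(n, m, td50, ...) ll_nat(n, m, td50))
  grid <- dplyr::arrange(grid, dplyr::desc(.data$ll))
  starts <- utils::head(grid, n_starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- if (free_n) {
      log(c(starts$n[i], starts$m[i], starts$td50[i]))
    } else {
      log(c(starts$m[i], starts$td50[i]))
    }
    res <- ascend(f, th0, box_lo, box_hi, tol = tol, max_iter = max_iter)
    if (is.null(best) || res$value > best$value) best <- res
  }

  th <- best$theta
  params <- if (free_n) {
    lkb_params(exp(th[1]), exp(th[2]), exp(th[3]))
  } else {
    lkb_params(fix_n, exp(th[1]), exp(th[2]))
  }
  grad <- best$gradient
  names(grad) <- if (free_n) c("n", "m", "td50") else c("m", "td50")
  if (!best$converged) {
    warn("LKB fit did not reach gradient tolerance; best iterate returned")
  }
  structure(
    list(
      params = params,
      log_likelihood = best$value,
      converged = best$converged,
      iterations = best$iterations,
      gradient = grad,
      fixed_n = if (free_n) NA_real_ else fix_n,
      outcome = outcome,
      n_patients = length(y)
    ),
    class = "lkb_fit"
  )
}

make_grid <- function(bounds, n_n, n_m, n_t, fix_n = NULL) {
  n_vals <- if (is.null(fix_n)) {
    exp(seq(log(bounds$n[1]), log(bounds$n[2]), length.out = n_n))
  } else {
    fix_n
  }
  tidyr::expand_grid(
    n = n_vals,
    m = exp(seq(log(bounds$m[1]), log(bounds$m[2]), length.out = n_m)),
    td50 = exp(seq(log(bounds$td50[1]), log(bounds$td50[2]), length.out = n_t))
  )
}

stack_dvhs <- function(dvhs) {
  n_pat <- length(dvhs)
  parts <- purrr::imap(dvhs, function(d, i) {
    keep <- d$dose_gy > 0 & d$volume_fraction > 0
    list(i = rep(i, sum(keep)), logd = log(d$dose_gy[keep]), v = d$volume_fraction[keep])
  })
  list(
    n_pat = n_pat,
    idx = unlist(purrr::map(parts, "i"), use.names = FALSE),
    logd = unlist(purrr::map(parts, "logd"), use.names = FALSE),
    v = unlist(purrr::map(parts, "v"), use.names = FALSE)
  )
}

stacked_geud <- function(st, n) {
  # doses <= 80 Gy and n >= 0.05 keep exp(logd / n) within double range
  s <- rowsum(st$v * exp(st$logd / n), st$idx)
  out <- numeric(st$n_pat)
  out[as.integer(rownames(s))] <- exp(n * log(s[, 1]))
  out
}

num_gradient <- function(f, th, h = 1e-6) {
  vapply(seq_along(th), function(j) {
    e <- replicate(length(th), 0)
    e[j] <- h
    (f(th + e) - f(th - e)) / (2 * h)
  }, numeric(1))
}

# projected gradient ascent on a box with backtracking line search;
# Barzilai-Borwein spectral step lengths give fast practical convergence
# on the correlated (m, TD50) likelihood surface
ascend <- function(f, th, lo, hi, tol, max_iter) {
  clamp <- function(x) pmin(pmax(x, lo), hi)
  th <- clamp(th)
  val <- f(th)
  g <- num_gradient(f, th)
  step <- 0.1
  iter <- 0L
  converged <- FALSE
  repeat {
    pg <- clamp(th + g) - th # projected gradient
    if (max(abs(pg)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    accepted <- FALSE
    t <- min(max(step, 1e-8), 10)
    while (t > 1e-14) {
      cand <- clamp(th + t * g)
      cand_val <- f(cand)
      if (cand_val >= val + 1e-4 * t * sum(pg^2)) {
        g_new <- num_gradient(f, cand)
        dth <- cand - th
        dg <- g_new - g
        # spectral step for the next iteration
        step <- if (sum(dg^2) > 0) abs(sum(dth * dg)) / sum(dg^2) else t * 2
        th <- cand
        val <- cand_val
        g <- g_new
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) {
      # no ascent step exists at line-search resolution: treat as stationary
      converged <- max(abs(pg)) < sqrt(tol)
      break
    }
  }
  list(theta = th, value = val, gradient = g, iterations = iter, converged = converged)
}

#' @export
print.lkb_fit <- function(x, ...) {
  cat(sprintf(
    "<lkb_fit> %s outcome, %d patients%s\n",
    x$outcome, x$n_patients,
    if (!is.na(x$fixed_n)) sprintf(", n fixed at %.3g", x$fixed_n) else ""
  ))
  print(x$params)
  cat(sprintf(
    "  log-likelihood %.3f nats, %sconverged in %d iterations\n",
    x$log_likelihood, if (x$converged) "" else "NOT ", x$iterations
  ))
  invisible(x)
}

#' Logistic regression fit of an NTCP model
#'
#' Fits a binomial logistic regression of a PCE endpoint on cohort
#' features via iteratively reweighted least squares ([stats::glm()]),
#' returning the model with odds ratios and Wald confidence intervals.
#'
#' @param cohort Cohort tibble.
#' @param features Character vector of cohort column names; may be empty
#'   for an intercept-only model.
#' @param outcome `"any"` or `"symptomatic"`.
#' @param level Confidence level for Wald intervals, default 0.95.
#' @return An object of class `pce_logistic` with elements `model`
#'   ([logistic_model()]), `log_likelihood`, `converged`, `iterations`,
#'   `selected_features`, `null_deviance`, `deviance`, `n_patients`.
#' @export
fit_logistic <- function(cohort, features, outcome = c("any", "symptomatic"),
                         level = 0.95) {
  outcome <- match.arg(outcome)
  y <- check_fit_feasible(outcome_vector(cohort, outcome))
  features <- as.character(features)
  for (fe in features) {
    if (!fe %in% names(cohort)) abort_contract(sprintf("no column '%s' in cohort", fe))
    if (length(unique(cohort[[fe]])) < 2L) {
      abort_degenerate(sprintf("feature '%s' is constant", fe))
    }
  }
  dat <- data.frame(.y = y, cohort[features], check.names = FALSE)
  form <- if (length(features) == 0L) {
    .y ~ 1
  } else {
    as.formula(paste(".y ~", paste(sprintf("`%s`", features), collapse = " + ")))
  }
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  cf <- coef(fit)
  if (!fit$converged || any(abs(cf[-1]) > 15)) {
    abort(
      "perfect or quasi-perfect separation: diverging coefficient estimates",
      class = "ntcppce_separation"
    )
  }
  model <- if (length(features) > 0L) {
    logistic_model(unname(cf[1]), setNames(unname(cf[-1]), features), vcov(fit))
  } else {
    # intercept-only: an empty coefficient vector, built directly
    structure(
      list(
        intercept = unname(cf[1]),
        coefficients = setNames(numeric(0), character(0)),
        covariance = vcov(fit)
      ),
      class = "logistic_model"
    )
  }
  structure(
    list(
      model = model,
      log_likelihood = as.numeric(logLik(fit)),
      converged = fit$converged,
      iterations = fit$iter,
      selected_features = NULL,
      features = features,
      outcome = outcome,
      level = level,
      null_deviance = fit$null.deviance,
      deviance = fit$deviance,
      n_patients = length(y)
    ),
    class = "pce_logistic"
  )
}

#' @export
print.pce_logistic <- function(x, ...) {
  cat(sprintf(
    "<pce_logistic> %s outcome, %d patients, log-likelihood %.3f\n",
    x$outcome, x$n_patients, x$log_likelihood
  ))
  if (length(x$model$coefficients) > 0L) {
    print(tidy.pce_logistic(x))
  } else {
    cat(sprintf("  intercept-only model, intercept %.4g\n", x$model$intercept))
  }
  invisible(x)
}

#' Forward stepwise logistic model selection by likelihood-ratio test
#'
#' Starting from an intercept-only model, repeatedly adds the candidate
#' feature giving the largest likelihood-ratio improvement whose LRT
#' p-value (chi-square, 1 df per added feature) is below `alpha`; stops
#' when no candidate qualifies. Ties in deviance improvement are broken by
#' lexicographic feature name, so selection is deterministic.
#'
#' @param cohort Cohort tibble.
#' @param candidates Candidate feature names (normally pre-screened by
#'   [univariate_screen()]).
#' @param outcome `"any"` or `"symptomatic"`.
#' @param alpha Entry significance level, default 0.05 (two-sided).
#' @return A `pce_logistic` fit of the selected model, with
#'   `selected_features` recording the entry order and `step_log` the
#'   per-step LRT details.
#' @export
forward_stepwise <- function(cohort, candidates, outcome = c("any", "symptomatic"),
                             alpha = 0.05) {
  outcome <- match.arg(outcome)
  y <- check_fit_feasible(outcome_vector(cohort, outcome))
  candidates <- sort(as.character(candidates))
  selected <- character(0)
  current <- fit_logistic(cohort, selected, outcome)
  steps <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    trials <- purrr::map(remaining, function(fe) {
      cand_fit <- tryCatch(
        fit_logistic(cohort, c(selected, fe), outcome),
        ntcppce_separation = function(e) NULL,
        ntcppce_degenerate_data = function(e) NULL
      )
      if (is.null(cand_fit)) return(NULL)
      lrt <- 2 * (cand_fit$log_likelihood - current$log_likelihood)
      tibble::tibble(
        feature = fe,
        lrt_statistic = lrt,
        p_value = pchisq(lrt, df = 1, lower.tail = FALSE)
      )
    })
    trials <- dplyr::bind_rows(purrr::compact(trials))
    if (nrow(trials) == 0L) break
    trials <- dplyr::arrange(trials, dplyr::desc(.data$lrt_statistic), .data$feature)
    best <- trials[1L, ]
    if (!(best$p_value < alpha)) break
    selected <- c(selected, best$feature)
    current <- fit_logistic(cohort, selected, outcome)
    steps[[length(steps) + 1L]] <- best
  }
  current$selected_features <- selected
  current$step_log <- dplyr::bind_rows(steps)
  current
}
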