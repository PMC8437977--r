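#' Analysis configuration
#'
#' Thresholds and settings of the full modelling pipeline. Defaults mirror
#' the published analysis: univariate entry screen at p < 0.10, forward
#' stepwise entry by likelihood-ratio test at p < 0.05 (two-sided),
#' collinearity screen at squared Pearson correlation > 0.70, 1000
#' bootstrap resamples for optimism correction, 10 Hosmer-Lemeshow groups.
#'
#' @param endpoints Endpoints to analyse (`"any"`, `"symptomatic"`).
#' @param candidates Candidate predictor columns; `NULL` uses every
#'   numeric cohort column besides identifiers, outcomes and latent
#'   probabilities.
#' @param p_univariate Univariate screen threshold, default 0.10.
#' @param alpha_stepwise Stepwise entry threshold, default 0.05.
#' @param r2_collinearity Collinearity threshold, default 0.70.
#' @param bootstrap_b Bootstrap resamples, default 1000.
#' @param hl_groups Hosmer-Lemeshow groups, default 10.
#' @param doses Dose grid (Gy) of the TD/NTCP summary table.
#' @param td_probs Probability grid of the TD section.
#' @param fit_lkb_free Also fit the free-n LKB model (requires DVHs)?
#' @param seed Seed for every stochastic stage.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(endpoints = c("any", "symptomatic"),
                            candidates = NULL,
                            p_univariate = 0.10,
                            alpha_stepwise = 0.05,
                            r2_collinearity = 0.70,
                            bootstrap_b = 1000L,
                            hl_groups = 10L,
                            doses = seq(10, 50, by = 10),
                            td_probs = c(0.05, 0.10, 0.25, 0.50),
                            fit_lkb_free = TRUE,
                            seed = 20150137L) {
  for (thr in c(p_univariate, alpha_stepwise, r2_collinearity)) {
    if (thr <= 0 || thr > 1) abort_config("screening thresholds must lie in (0, 1]")
  }
  if (bootstrap_b < 1L) abort_config("bootstrap_b must be at least 1")
  structure(
    list(
      endpoints = match.arg(endpoints, several.ok = TRUE),
      candidates = candidates,
      p_univariate = p_univariate,
      alpha_stepwise = alpha_stepwise,
      r2_collinearity = r2_collinearity,
      bootstrap_b = as.integer(bootstrap_b),
      hl_groups = as.integer(hl_groups),
      doses = doses,
      td_probs = td_probs,
      fit_lkb_free = isTRUE(fit_lkb_free),
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

default_candidates <- function(cohort) {
  drop <- c(
    "patient_id", "outcome_any_grade", "outcome_symptomatic",
    "p_any", "p_sym", "dvh"
  )
  keep <- setdiff(names(cohort), drop)
  keep[vapply(keep, function(cl) is.numeric(cohort[[cl]]), logical(1))]
}

#' Run the full NTCP modelling pipeline
#'
#' Executes, per endpoint: univariate screen, collinearity screen (within
#' each collinear cluster the feature with the best univariate AUC is
#' kept), forward stepwise logistic fit, the MHD-based probit fit
#' (n fixed at 1), optionally the free-n LKB fit on DVHs, validation
#' (apparent AUC with bootstrap CI, bootstrap optimism-corrected AUC for
#' the logistic model, Hosmer-Lemeshow calibration for every model,
#' MHD-vs-LKB agreement), and the TD/NTCP summary table. Deterministic
#' given the configuration seed.
#'
#' @param cohort Cohort tibble.
#' @param config An [analysis_config()].
#' @return An object of class `ntcp_report`: per-endpoint results
#'   (`screen`, `collinearity`, `logistic`, `probit_mhd`, `lkb`,
#'   `validation`, `agreement`, `td_table`) plus the config and seed.
#' @export
run_pipeline <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (config$bootstrap_b < 50L) {
    warn(sprintf(
      "bootstrap_b = %d is too small for a stable optimism estimate",
      config$bootstrap_b
    ))
  }
  candidates <- config$candidates %||% default_candidates(cohort)
  endpoints <- config$endpoints
  results <- purrr::map(endpoints, function(ep) {
    run_endpoint(cohort, ep, candidates, config)
  })
  names(results) <- endpoints
  structure(
    list(endpoints = results, config = config, seed = config$seed),
    class = "ntcp_report"
  )
}

run_endpoint <- function(cohort, endpoint, candidates, config) {
  y <- outcome_vector(cohort, endpoint)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' (%s endpoint) failed: %s",
        name, endpoint, conditionMessage(e)), parent = e)
    })
  }

  screen <- stage("univariate_screen",
    univariate_screen(cohort, candidates, endpoint, config$p_univariate))
  retained <- screen$feature[screen$retained]

  clusters <- if (length(retained) >= 2L) {
    stage("collinearity_screen",
      collinearity_screen(cohort, retained, config$r2_collinearity))
  } else {
    tibble::tibble(feature = character(0), cluster = integer(0))
  }
  pruned <- retained
  if (nrow(clusters) > 0L) {
    for (cl in unique(clusters$cluster)) {
      members <- clusters$feature[clusters$cluster == cl]
      aucs <- vapply(members, function(fe) auc_scalar(cohort[[fe]], y), numeric(1))
      aucs <- pmax(aucs, 1 - aucs) # direction-free discrimination
      keep <- members[order(-aucs, members)][1L]
      pruned <- setdiff(pruned, setdiff(members, keep))
    }
  }

  logistic <- stage("forward_stepwise",
    forward_stepwise(cohort, pruned, endpoint, config$alpha_stepwise))

  probit_mhd <- stage("fit_lkb_mhd", fit_lkb(cohort, endpoint, fix_n = 1))
  lkb <- if (config$fit_lkb_free && "dvh" %in% names(cohort)) {
    stage("fit_lkb_free", fit_lkb(cohort, endpoint))
  } else {
    NULL
  }

  validation <- stage("validation", {
    models <- list(logistic = logistic$model, probit_mhd = probit_mhd$params)
    if (!is.null(lkb)) models$lkb <- lkb$params
    rows <- purrr::imap(models, function(mod, nm) {
      p <- predict_ntcp(mod, cohort)
      a <- roc_auc(p, y, B = min(config$bootstrap_b, 2000L), seed = config$seed)
      hl <- hosmer_lemeshow(
        pmin(pmax(p, 1e-12), 1 - 1e-12), y, g = config$hl_groups)
      tibble::tibble(
        model = nm,
        auc = a$auc, auc_low = a$conf_low, auc_high = a$conf_high,
        hl_chi_squared = hl$chi_squared, hl_p = hl$p_value
      )
    })
    tab <- dplyr::bind_rows(rows)
    if (length(logistic$model$coefficients) > 0L) {
      opt <- bootstrap_optimism(
        cohort, logistic_spec(logistic$selected_features, endpoint),
        endpoint, B = config$bootstrap_b, seed = config$seed
      )
      tab$adjusted_auc <- ifelse(tab$model == "logistic", opt$adjusted_auc, NA_real_)
      tab$mean_optimism <- ifelse(tab$model == "logistic", opt$mean_optimism, NA_real_)
    }
    tab
  })

  agreement <- if (!is.null(lkb)) {
    stage("agreement", compare_models(
      predict_ntcp(probit_mhd$params, cohort),
      predict_ntcp(lkb$params, cohort)
    ))
  } else {
    NULL
  }

  td_models <- list(probit_mhd = probit_mhd$params)
  if (!is.null(lkb)) td_models$lkb <- lkb$params
  if (length(logistic$model$coefficients) == 1L) {
    td_models$logistic <- logistic$model
  }
  td_table <- stage("td_table",
    render_td_ntcp_table(td_models, config$doses, config$td_probs))

  list(
    endpoint = endpoint,
    screen = screen,
    collinearity = clusters,
    features = pruned,
    logistic = logistic,
    probit_mhd = probit_mhd,
    lkb = lkb,
    validation = validation,
    agreement = agreement,
    td_table = td_table
  )
}

#' Render a TD / NTCP summary table
#'
#' Publication-style summary: one column per model, a tolerance-dose (TD)
#' section with the dose reaching each target probability (via
#' [invert_td()]; a not-achieved TD is `NA`, rendered as a dash), and an
#' NTCP section with the modelled probability at each grid dose. TD values
#' are rounded to 1 decimal and probabilities to 2, the reporting
#' convention of the summary tables.
#'
#' @param models Named list of [lkb_params()] / [logistic_model()] objects
#'   (or `lkb_fit` / `pce_logistic` fits, whose parameters are taken).
#' @param doses Dose grid in Gy for the NTCP section.
#' @param probabilities Probability grid for the TD section; empty to omit
#'   the section.
#' @param dose_feature,profile Passed to [invert_td()] for multivariable
#'   logistic models.
#' @return A tibble with columns `section`, `level`, and one column per
#'   model.
#' @export
render_td_ntcp_table <- function(models, doses, probabilities,
                                 dose_feature = NULL, profile = NULL) {
  if (length(models) == 0L || is.null(names(models))) {
    abort_contract("models must be a non-empty named list")
  }
  models <- purrr::map(models, function(m) {
    if (inherits(m, "lkb_fit")) m$params else if (inherits(m, "pce_logistic")) m$model else m
  })
  td_rows <- if (length(probabilities) > 0L) {
    cols <- purrr::map(models, function(m) {
      round(invert_td(m, probabilities, dose_feature = dose_feature, profile = profile), 1)
    })
    tibble::tibble(
      section = "TD (Gy)",
      level = sprintf("%g%%", 100 * probabilities),
      !!!cols
    )
  } else {
    NULL
  }
  ntcp_rows <- if (length(doses) > 0L) {
    cols <- purrr::map(models, function(m) {
      p <- if (inherits(m, "lkb_params")) {
        probit_ntcp(doses, m)
      } else {
        vapply(doses, function(d) {
          feats <- c(setNames(d, names(m$coefficients)[1]), unlist(profile))
          if (length(m$coefficients) > 1L && !is.null(dose_feature)) {
            feats <- c(setNames(d, dose_feature), unlist(profile))
          }
          logistic_ntcp(feats, m)
        }, numeric(1))
      }
      round(p, 2)
    })
    tibble::tibble(
      section = "NTCP (probability)",
      level = sprintf("%g Gy", doses),
      !!!cols
    )
  } else {
    NULL
  }
  dplyr::bind_rows(td_rows, ntcp_rows)
}

#' @export
print.ntcp_report <- function(x, ...) {
  cat(sprintf("<ntcp_report> seed %d\n", x$seed))
  for (ep in names(x$endpoints)) {
    res <- x$endpoints[[ep]]
    cat(sprintf("\n== %s endpoint ==\n", ep))
    cat(sprintf(
      "selected features: %s\n",
      if (length(res$logistic$selected_features) > 0L) {
        paste(res$logistic$selected_features, collapse = ", ")
      } else {
        "(none)"
      }
    ))
    cat("\nvalidation:\n")
    print(res$validation)
    cat("\nTD / NTCP summary:\n")
    print(res$td_table, n = Inf)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
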