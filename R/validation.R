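#' Area under the ROC curve
#'
#' AUC computed as the Mann-Whitney U statistic divided by the number of
#' event/non-event pairs, with ties counted one half (midrank convention).
#' The 95% confidence interval is a stratified bootstrap percentile
#' interval: events and non-events are resampled separately so every
#' replicate keeps both classes.
#'
#' @param scores Continuous risk scores.
#' @param labels Binary outcomes (0/1).
#' @param conf Compute a bootstrap confidence interval?
#' @param B Bootstrap replicates for the interval, default 2000.
#' @param level Confidence level, default 0.95.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble with `auc`, and `conf_low`/`conf_high` when
#'   `conf = TRUE`.
#' @export
roc_auc <- function(scores, labels, conf = TRUE, B = 2000L, level = 0.95,
                    seed = 20150137L) {
  if (length(scores) != length(labels)) abort_contract("lengths must match")
  if (length(unique(labels)) < 2L) {
    abort_degenerate("AUC needs both an event and a non-event")
  }
  a <- auc_scalar(scores, labels)
  if (!conf) {
    return(tibble::tibble(auc = a))
  }
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
        sample(neg, length(neg), replace = TRUE))
      auc_scalar(scores[i], labels[i])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(auc = a, conf_low = qs[1], conf_high = qs[2])
}

auc_scalar <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate logistic screen of candidate predictors
#'
#' Fits a single-predictor logistic regression per candidate and retains
#' those with Wald p-value below `p_cut` (default 0.10), the entry screen
#' ahead of multivariable modelling.
#'
#' @param cohort Cohort tibble.
#' @param candidates Candidate feature names (cohort columns).
#' @param outcome `"any"` or `"symptomatic"`.
#' @param p_cut Retention threshold, default 0.10.
#' @return A tibble with `feature`, `coefficient`, `p_value`, `retained`.
#' @export
univariate_screen <- function(cohort, candidates, outcome = c("any", "symptomatic"),
                              p_cut = 0.10) {
  outcome <- match.arg(outcome)
  check_fit_feasible(outcome_vector(cohort, outcome))
  purrr::map(as.character(candidates), function(fe) {
    fit <- tryCatch(fit_logistic(cohort, fe, outcome),
      ntcppce_separation = function(e) NULL
    )
    if (is.null(fit)) {
      # separation: infinitely strong association; retain with p ~ 0
      return(tibble::tibble(feature = fe, coefficient = Inf, p_value = 0))
    }
    se <- sqrt(diag(fit$model$covariance))[2L]
    z <- fit$model$coefficients[[1L]] / se
    tibble::tibble(
      feature = fe,
      coefficient = fit$model$coefficients[[1L]],
      p_value = 2 * pnorm(-abs(z))
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(retained = .data$p_value < p_cut)
}

#' Pairwise collinearity screen
#'
#' Groups features whose squared Pearson correlation exceeds `r2_cut`
#' (default 0.70) into clusters by transitive closure, mirroring the
#' multicollinearity check applied to the highly correlated cardiac
#' dose-volume metrics. Constant features are excluded with a warning.
#'
#' @param cohort Cohort tibble.
#' @param features Feature names, at least two.
#' @param r2_cut Squared-correlation threshold, default 0.70.
#' @return A tibble with `feature` and integer `cluster` for every feature
#'   in a cluster of two or more; zero rows when no collinearity is found.
#' @export
collinearity_screen <- function(cohort, features, r2_cut = 0.70) {
  features <- as.character(features)
  if (length(features) < 2L) abort_contract("need at least two features")
  keep <- vapply(features, function(fe) sd(cohort[[fe]]) > 0, logical(1))
  if (any(!keep)) {
    warn(sprintf(
      "constant feature(s) excluded from collinearity screen: %s",
      paste(features[!keep], collapse = ", ")
    ))
  }
  features <- features[keep]
  if (length(features) < 2L) {
    return(tibble::tibble(feature = character(0), cluster = integer(0)))
  }
  r2 <- cor(as.matrix(cohort[features]))^2
  # union-find over the pairs above threshold
  parent <- seq_along(features)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_along(features)) {
    for (j in seq_len(i - 1L)) {
      if (r2[i, j] > r2_cut) parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_along(features), find, integer(1))
  sizes <- table(root)
  multi <- as.integer(names(sizes)[sizes >= 2])
  if (length(multi) == 0L) {
    return(tibble::tibble(feature = character(0), cluster = integer(0)))
  }
  tibble::tibble(
    feature = features[root %in% multi],
    cluster = match(root[root %in% multi], multi)
  ) |>
    dplyr::arrange(.data$cluster, .data$feature)
}

#' Logistic refitting recipe for bootstrap validation
#'
#' Packages "refit this logistic model" as a function of a training
#' cohort, returning a scorer for any cohort. Bootstrap refits tolerate
#' separation (coefficients may diverge; ranking, hence AUC, is still
#' defined).
#'
#' @param features Feature names.
#' @param outcome `"any"` or `"symptomatic"`.
#' @return A function `cohort -> (cohort -> scores)`.
#' @export
logistic_spec <- function(features, outcome = c("any", "symptomatic")) {
  outcome <- match.arg(outcome)
  features <- as.character(features)
  function(train) {
    y <- outcome_vector(train, outcome)
    dat <- data.frame(.y = y, train[features], check.names = FALSE)
    form <- as.formula(paste(".y ~", paste(sprintf("`%s`", features), collapse = " + ")))
    fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
    beta <- coef(fit)
    function(newdata) {
      x <- cbind(1, as.matrix(newdata[features]))
      as.numeric(plogis(x %*% beta))
    }
  }
}

#' Bootstrap optimism-corrected AUC
#'
#' TRIPOD-style internal validation: the modelling recipe is refitted on
#' each of `B` bootstrap resamples (drawn with replacement at cohort size);
#' per resample the optimism is the AUC of the refitted model on its own
#' resample minus its AUC on the original cohort. The adjusted AUC is the
#' apparent AUC minus the mean optimism. Resamples containing a single
#' outcome class are redrawn (and counted).
#'
#' @param cohort Cohort tibble.
#' @param model_spec A refitting recipe: a function `cohort -> scorer`,
#'   e.g. [logistic_spec()]. A recipe that ignores its training data (a
#'   fixed score) has zero optimism by construction.
#' @param outcome `"any"` or `"symptomatic"`.
#' @param B Bootstrap replicates, default 1000.
#' @param seed Resampling seed.
#' @return A one-row tibble: `apparent_auc`, `mean_optimism`,
#'   `adjusted_auc`, `b`, `redraws`.
#' @export
bootstrap_optimism <- function(cohort, model_spec, outcome = c("any", "symptomatic"),
                               B = 1000L, seed = 20150137L) {
  outcome <- match.arg(outcome)
  y <- check_fit_feasible(outcome_vector(cohort, outcome))
  n <- nrow(cohort)
  scorer0 <- model_spec(cohort)
  apparent <- auc_scalar(scorer0(cohort), y)
  redraws <- 0L
  optimism <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (length(unique(yb)) == 2L) break
        redraws <<- redraws + 1L
      }
      boot <- cohort[idx, , drop = FALSE]
      scorer <- model_spec(boot)
      auc_scalar(scorer(boot), yb) - auc_scalar(scorer(cohort), y)
    }, numeric(1))
  })
  if (redraws > 0L) {
    inform(sprintf("%d single-class bootstrap resample(s) redrawn", redraws))
  }
  tibble::tibble(
    apparent_auc = apparent,
    mean_optimism = mean(optimism),
    adjusted_auc = apparent - mean(optimism),
    b = B,
    redraws = redraws
  )
}

#' Hosmer-Lemeshow calibration test
#'
#' Patients are ranked by predicted probability into `g` near-equal groups
#' (identical predictions stay in the same group); the statistic sums
#' `(observed - expected)^2 / expected` over groups for both the event and
#' non-event cells, and is referred to a chi-square distribution with
#' `df` degrees of freedom (default `g - 2`, the convention for fitted
#' models; use `df = g` when the probabilities were not estimated from the
#' same data).
#'
#' @param predictions Predicted probabilities in (0, 1).
#' @param outcomes Binary outcomes.
#' @param g Number of risk groups, at least 3, default 10.
#' @param df Degrees of freedom for the reference chi-square.
#' @return An object of class `hl_test` with `chi_squared`, `p_value`,
#'   `groups`, `df`, and a per-group calibration table `bins`
#'   (`mean_predicted`, `observed_rate`, `n`); [tidy()] returns the bins,
#'   [glance()] the statistic.
#' @export
hosmer_lemeshow <- function(predictions, outcomes, g = 10L, df = g - 2L) {
  if (length(predictions) != length(outcomes)) abort_contract("lengths must match")
  if (g < 3L) abort_contract("need at least 3 groups")
  if (any(predictions <= 0 | predictions >= 1)) {
    abort_domain("predictions must lie strictly in (0, 1)")
  }
  uniq <- sort(unique(predictions))
  if (length(uniq) < 2L) {
    abort_degenerate("predictions too concentrated to form risk groups")
  }
  grp <- if (length(uniq) <= g) {
    # few distinct risk levels: each level is its own group (ties together)
    match(predictions, uniq)
  } else {
    breaks <- unique(quantile(predictions, probs = seq(0, 1, length.out = g + 1)))
    cut(predictions, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  bins <- tibble::tibble(p = predictions, y = outcomes, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      n = dplyr::n(),
      observed = sum(.data$y),
      expected = sum(.data$p),
      mean_predicted = mean(.data$p),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_predicted)
  # merge groups whose expected count (events or non-events) is zero
  merged <- 0L
  i <- 1L
  while (i <= nrow(bins)) {
    e1 <- bins$expected[i]
    e0 <- bins$n[i] - bins$expected[i]
    if ((e1 <= 0 || e0 <= 0) && nrow(bins) > 1L) {
      j <- if (i == nrow(bins)) i - 1L else i + 1L
      bins$n[j] <- bins$n[j] + bins$n[i]
      bins$observed[j] <- bins$observed[j] + bins$observed[i]
      bins$expected[j] <- bins$expected[j] + bins$expected[i]
      bins <- bins[-i, ]
      merged <- merged + 1L
    } else {
      i <- i + 1L
    }
  }
  if (merged > 0L) inform(sprintf("%d group(s) with empty expected cell merged", merged))
  bins$mean_predicted <- bins$expected / bins$n
  chi2 <- sum(
    (bins$observed - bins$expected)^2 / bins$expected +
      ((bins$n - bins$observed) - (bins$n - bins$expected))^2 /
        (bins$n - bins$expected)
  )
  structure(
    list(
      chi_squared = chi2,
      p_value = pchisq(chi2, df = df, lower.tail = FALSE),
      groups = nrow(bins),
      df = df,
      bins = tibble::tibble(
        mean_predicted = bins$mean_predicted,
        observed_rate = bins$observed / bins$n,
        n = bins$n
      )
    ),
    class = "hl_test"
  )
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow: chi-squared = %.2f on %d df (%d groups), p = %.3f\n",
    x$chi_squared, x$df, x$groups, x$p_value
  ))
  invisible(x)
}

#' Agreement between two models' predictions
#'
#' Ordinary least-squares regression of model B's predictions on model A's,
#' with the coefficient of determination of the fit ([r_squared()]); used
#' to quantify the correspondence between the MHD-based and LKB NTCP
#' models.
#'
#' @param preds_a Predictions of the reference model (regressor).
#' @param preds_b Predictions of the comparison model (response).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`.
#' @export
compare_models <- function(preds_a, preds_b) {
  if (length(preds_a) != length(preds_b)) abort_contract("lengths must match")
  if (length(preds_a) < 3L) abort_contract("need at least three points")
  if (sd(preds_a) == 0) abort_domain("reference predictions are constant")
  fit <- lm(preds_b ~ preds_a)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r_squared(preds_b, fitted(fit))
  )
}
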