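test_that("binomial log-likelihood matches hand sums and is bounded", {
  expect_equal(binary_log_likelihood(0.5, 1), -0.693147, tolerance = 1e-6)
  expect_equal(
    binary_log_likelihood(c(0.2, 0.5, 0.9), c(0, 1, 1)),
    log(0.8) + log(0.5) + log(0.9),
    tolerance = 1e-9
  )
  expect_equal(binary_log_likelihood(c(0.2, 0.5, 0.9), c(0, 1, 1)), -1.02165,
    tolerance = 1e-5)
  # perfect prediction approaches 0 at the clipping bound
  expect_gte(binary_log_likelihood(c(1, 1, 0), c(1, 1, 0)), -1e-6)
  expect_lte(binary_log_likelihood(runif(10), rbinom(10, 1, 0.5)), 0)
  expect_error(binary_log_likelihood(c(0.5, 0.5), 1), class = "ntcppce_contract_error")
})

test_that("LKB fit recovers the generating parameters of an MHD probit truth", {
  truth <- ref_models()$apce_probit_mhd # n = 1, m = 0.75, TD50 = 34.3
  cfg <- synthetic_config(n_patients = 1000, truth_any = truth, dvh = FALSE)
  fits <- purrr::map(1:3, function(i) {
    co <- generate_cohort(cfg, seed = 300 + i)
    fit_lkb(co, "any", fix_n = 1)
  })
  td50 <- vapply(fits, function(f) f$params$td50, numeric(1))
  m <- vapply(fits, function(f) f$params$m, numeric(1))
  expect_lt(abs(median(td50) - 34.3), 3)
  expect_lt(abs(median(m) - 0.75), 0.15)
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  # log-likelihood of a binary fit is negative
  expect_true(all(vapply(fits, function(f) f$log_likelihood, numeric(1)) < 0))
})

test_that("free-n LKB fit recovers volume-effect truth from DVH cohorts", {
  truth <- lkb_params(n = 0.4, m = 0.3, td50 = 50)
  cfg <- synthetic_config(n_patients = 500, truth_any = truth, dvh = TRUE)
  fits <- purrr::map(1:5, function(i) {
    co <- generate_cohort(cfg, seed = 400 + i)
    fit_lkb(co, "any")
  })
  td50 <- vapply(fits, function(f) f$params$td50, numeric(1))
  m <- vapply(fits, function(f) f$params$m, numeric(1))
  expect_lt(abs(median(td50) - 50), 5)
  expect_lt(abs(median(m) - 0.3), 0.1)
})

test_that("the optimum is a true local maximum (profile and oracle checks)", {
  cfg <- synthetic_config(n_patients = 229)
  co <- generate_cohort(cfg, seed = 5)
  fit <- fit_lkb(co, "any")
  # re-fitting with n fixed at the free optimum reproduces (m, TD50)
  prof <- fit_lkb(co, "any", fix_n = fit$params$n)
  expect_equal(prof$params$m, fit$params$m, tolerance = 1e-3)
  expect_equal(prof$params$td50, fit$params$td50, tolerance = 1e-3)
  # independent optimiser agreement on the same likelihood surface
  y <- co$outcome_any_grade
  nll <- function(p) {
    d <- vapply(co$dvh, geud, numeric(1), n = exp(p[1]))
    -binary_log_likelihood(pnorm((d - exp(p[3])) / (exp(p[2] + p[3]))), y)
  }
  o <- stats::optim(log(c(fit$params$n, fit$params$m, fit$params$td50)), nll,
    method = "L-BFGS-B", lower = log(c(0.05, 0.05, 5)), upper = log(c(2, 2, 120)))
  expect_lte(abs(-o$value - fit$log_likelihood), 0.01)
})

test_that("the n parameter is reported flat when dose is uniform", {
  cfg <- synthetic_config(n_patients = 150, dvh = TRUE, dvh_heterogeneity = 0)
  co <- generate_cohort(cfg, seed = 9)
  fit <- fit_lkb(co, "any")
  # uniform dose makes gEUD independent of n: near-zero n-gradient
  expect_lt(abs(fit$gradient[["n"]]), 1e-4)
  expect_s3_class(fit$params, "lkb_params")
})

test_that("degenerate outcome vectors are rejected", {
  cfg <- synthetic_config(n_patients = 30, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 2)
  co$outcome_any_grade <- 1L
  expect_error(fit_lkb(co, "any", fix_n = 1), class = "ntcppce_degenerate_data")
  expect_error(fit_logistic(co, "mhd", "any"), class = "ntcppce_degenerate_data")
})

test_that("logistic regression recovers generating coefficients", {
  truth <- ref_models()$apce_logistic
  cfg <- synthetic_config(n_patients = 2000, truth_any = truth, dvh = FALSE)
  coefs <- vapply(1:20, function(i) {
    co <- generate_cohort(cfg, seed = 500 + i)
    fit_logistic(co, "mhd", "any")$model$coefficients[["mhd"]]
  }, numeric(1))
  expect_lt(abs(median(coefs) - 0.073), 0.015)

  # independence: coefficient near zero when the outcome ignores the feature
  cfg0 <- synthetic_config(
    n_patients = 5000,
    truth_any = logistic_model(qlogis(0.3), c(hypertension = 0)),
    dvh = FALSE
  )
  co0 <- generate_cohort(cfg0, seed = 77)
  f0 <- fit_logistic(co0, "mhd", "any")
  expect_lt(abs(f0$model$coefficients[["mhd"]]), 0.05)
})

test_that("odds ratios and Wald intervals are consistent with coefficients", {
  cfg <- synthetic_config(n_patients = 400, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 21)
  fit <- fit_logistic(co, c("mhd", "hypertension"), "any")
  td <- tidy(fit)
  expect_equal(td$odds.ratio, exp(td$estimate), tolerance = 1e-9)
  expect_equal(odds_ratios(fit$model), exp(fit$model$coefficients), tolerance = 1e-12)
  expect_true(all(td$conf.low < td$odds.ratio & td$odds.ratio < td$conf.high))
  gl <- glance(fit)
  expect_lte(gl$logLik, 0)
  expect_true(gl$converged)
})

test_that("perfect separation raises a diverging-coefficient error", {
  co <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:40),
    mhd = c(seq(1, 20), seq(41, 60)),
    outcome_any_grade = rep(c(0L, 1L), each = 20),
    outcome_symptomatic = 0L
  )
  expect_error(fit_logistic(co, "mhd", "any"), class = "ntcppce_separation")
})

test_that("forward stepwise selects the true predictor among noise", {
  n <- 1000
  hits <- vapply(1:100, function(i) {
    co <- withr::with_seed(600 + i, {
      x <- rnorm(n)
      noise <- matrix(rnorm(n * 4), n, 4)
      colnames(noise) <- paste0("z", 1:4)
      y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
      tibble::tibble(
        patient_id = as.character(seq_len(n)), signal = x,
        tibble::as_tibble(noise),
        outcome_any_grade = y, outcome_symptomatic = 0L
      )
    })
    sel <- forward_stepwise(co, c("signal", paste0("z", 1:4)), "any")$selected_features
    length(sel) >= 1 && sel[1] == "signal"
  }, logical(1))
  # the true predictor always leads the selection; noise features may
  # occasionally join afterwards at the nominal entry rate
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise entry of pure-noise candidates is controlled", {
  n <- 1000
  entries <- purrr::map(1:60, function(i) {
    co <- withr::with_seed(700 + i, {
      noise <- matrix(rnorm(n * 4), n, 4)
      colnames(noise) <- paste0("z", 1:4)
      tibble::tibble(
        patient_id = as.character(seq_len(n)),
        tibble::as_tibble(noise),
        outcome_any_grade = rbinom(n, 1, 0.4), outcome_symptomatic = 0L
      )
    })
    forward_stepwise(co, paste0("z", 1:4), "any")$selected_features
  })
  rate_per_candidate <- vapply(paste0("z", 1:4), function(z) {
    mean(vapply(entries, function(e) z %in% e, logical(1)))
  }, numeric(1))
  expect_true(all(rate_per_candidate <= 0.10))
})

test_that("a degenerate entry threshold admits every candidate", {
  cfg <- synthetic_config(n_patients = 300, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 31)
  fit <- forward_stepwise(co, c("mhd", "hypertension"), "any", alpha = 1.0)
  expect_setequal(fit$selected_features, c("mhd", "hypertension"))
  # entry order follows likelihood-ratio gain
  expect_equal(fit$selected_features[1], fit$step_log$feature[1])
  # empty candidate list falls back to the intercept-only model
  empty <- forward_stepwise(co, character(0), "any")
  expect_length(empty$model$coefficients, 0)
  expect_equal(plogis(empty$model$intercept), mean(co$outcome_any_grade),
    tolerance = 1e-6)
})
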