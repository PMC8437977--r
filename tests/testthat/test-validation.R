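# exhaustive pair-counting AUC: P(score_event > score_nonevent) + 0.5 ties
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1), conf = FALSE)$auc, 1)
  expect_equal(roc_auc(1:4, c(0, 1, 0, 1), conf = FALSE)$auc, 0.75)
  for (i in 1:20) {
    withr::with_seed(800 + i, {
      n <- sample(4:50, 1)
      scores <- sample(round(rnorm(n), 1)) # coarse values force ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(
        roc_auc(scores, labels, conf = FALSE)$auc,
        auc_pairs(scores, labels),
        tolerance = 1e-12
      )
    })
  }
  expect_error(roc_auc(1:4, rep(1, 4)), class = "ntcppce_degenerate_data")
})

test_that("AUC of uninformative scores is one half with a sane bootstrap CI", {
  withr::with_seed(11, {
    scores <- rnorm(2000)
    labels <- rbinom(2000, 1, 0.4)
  })
  out <- roc_auc(scores, labels, B = 500, seed = 12)
  expect_lt(abs(out$auc - 0.5), 0.03)
  expect_lt(out$conf_low, out$auc)
  expect_gt(out$conf_high, out$auc)
})

test_that("univariate screen retains real predictors and controls noise", {
  cfg <- synthetic_config(n_patients = 500, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 41)
  scr <- univariate_screen(co, c("mhd", "hypertension"), "any")
  expect_true(scr$retained[scr$feature == "mhd"])
  # a zero cut-off retains nothing
  scr0 <- univariate_screen(co, "mhd", "any", p_cut = 0)
  expect_false(any(scr0$retained))
  # pure-noise retention rate is close to the nominal 10%
  n <- 300
  rates <- vapply(1:200, function(i) {
    withr::with_seed(900 + i, {
      co2 <- tibble::tibble(
        patient_id = as.character(1:n), z = rnorm(n),
        outcome_any_grade = rbinom(n, 1, 0.4), outcome_symptomatic = 0L
      )
    })
    univariate_screen(co2, "z", "any")$retained
  }, logical(1))
  expect_gt(mean(rates), 0.04)
  expect_lt(mean(rates), 0.17)
})

test_that("collinearity screen clusters by transitive closure", {
  withr::with_seed(51, {
    n <- 1000
    x <- rnorm(n)
    co <- tibble::tibble(
      patient_id = as.character(1:n),
      a = x,
      a_dup = x, # identical copy
      b = 0.9 * x + rnorm(n, sd = sqrt(0.81 * (1 / 0.81 - 1))), # true r2 ~ 0.81
      c = rnorm(n),
      d = rnorm(n)
    )
  })
  cl <- collinearity_screen(co, c("a", "a_dup", "b", "c", "d"))
  expect_setequal(cl$feature, c("a", "a_dup", "b"))
  expect_length(unique(cl$cluster), 1)
  # independent features do not cluster
  for (i in 1:20) {
    withr::with_seed(1000 + i, {
      ind <- tibble::as_tibble(matrix(rnorm(1000 * 5), 1000, 5,
        dimnames = list(NULL, paste0("f", 1:5))))
    })
    expect_equal(nrow(collinearity_screen(ind, paste0("f", 1:5))), 0)
  }
  co$k <- 1
  expect_warning(collinearity_screen(co, c("a", "b", "k")), "constant")
})

test_that("bootstrap optimism is zero for fixed scores and rank-invariant", {
  cfg <- synthetic_config(n_patients = 120, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 61)
  fixed_spec <- function(train) function(newdata) newdata$mhd
  out <- bootstrap_optimism(co, fixed_spec, "any", B = 100, seed = 62)
  # a fixed score has zero optimism in expectation: only resampling noise
  expect_lt(abs(out$mean_optimism), 0.01)
  expect_equal(out$adjusted_auc, out$apparent_auc - out$mean_optimism)
  # invariant under monotone rescaling of the scores
  exp_spec <- function(train) function(newdata) exp(newdata$mhd / 10)
  out2 <- bootstrap_optimism(co, exp_spec, "any", B = 100, seed = 62)
  expect_equal(out2$apparent_auc, out$apparent_auc, tolerance = 1e-12)
  expect_equal(out2$mean_optimism, out$mean_optimism, tolerance = 1e-12)
})

test_that("optimism is small for a well-specified single-predictor model", {
  cfg <- synthetic_config(n_patients = 1000, dvh = FALSE)
  co <- generate_cohort(cfg, seed = 63)
  out <- bootstrap_optimism(co, logistic_spec("mhd", "any"), "any",
    B = 200, seed = 64)
  expect_lt(abs(out$mean_optimism), 0.01)
})

test_that("Hosmer-Lemeshow is zero on exactly calibrated groups", {
  p <- c(rep(0.2, 10), rep(0.8, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(p, y, g = 3)
  expect_equal(hl$chi_squared, 0, tolerance = 1e-12)
  expect_equal(hl$groups, 2) # tied predictions stay together
  expect_error(hosmer_lemeshow(p, y, g = 2), class = "ntcppce_contract_error")
  expect_error(hosmer_lemeshow(rep(0.5, 10), rbinom(10, 1, 0.5), g = 4),
    class = "ntcppce_degenerate_data")
  # non-negative in general, with a calibration table that sums to n
  withr::with_seed(71, {
    p2 <- runif(200, 0.1, 0.9)
    y2 <- rbinom(200, 1, p2)
  })
  hl2 <- hosmer_lemeshow(p2, y2, g = 10)
  expect_gte(hl2$chi_squared, 0)
  expect_equal(sum(tidy(hl2)$n), 200)
  expect_equal(glance(hl2)$df, 8)
})

test_that("models that agree produce identity-line regressions", {
  p <- seq(0.1, 0.9, length.out = 20)
  out <- compare_models(p, p)
  expect_equal(out$slope, 1, tolerance = 1e-12)
  expect_equal(out$intercept, 0, tolerance = 1e-12)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_lt(compare_models(p, rev(p))$slope, 0)
  expect_error(compare_models(rep(0.3, 5), p[1:5]), class = "ntcppce_domain_error")
})

test_that("MHD-based and LKB predictions correspond on concentrated DVHs", {
  m <- ref_models()
  cfg <- synthetic_config(n_patients = 150, dvh = TRUE, dvh_heterogeneity = 1)
  co <- generate_cohort(cfg, seed = 81)
  p_mhd <- predict_ntcp(m$apce_probit_mhd, co)
  lkb_like <- lkb_params(0.4, m$apce_probit_mhd$m, m$apce_probit_mhd$td50)
  p_lkb <- predict_ntcp(lkb_like, co)
  expect_gt(compare_models(p_mhd, p_lkb)$r_squared, 0.9)
})
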