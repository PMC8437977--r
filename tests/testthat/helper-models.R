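# Reference NTCP parameter sets for the oesophageal-cancer chemoradiotherapy
# cohort: the fitted mean-heart-dose (MHD) logistic and probit models and the
# gEUD-based LKB models, for the any-grade (A-PCE) and symptomatic (S-PCE)
# pericardial effusion endpoints. Used as ground truth for simulation and as
# fixed inputs for forward-model checks.
ref_models <- function() {
  list(
    apce_logistic = logistic_model(-2.513, c(mhd = 0.073)),
    spce_logistic = logistic_model(-7.240, c(mhd = 0.161, hypertension = -1.858)),
    apce_probit_mhd = lkb_params(n = 1, m = 0.75, td50 = 34.3),
    spce_probit_mhd = lkb_params(n = 1, m = 0.26, td50 = 56.5),
    apce_lkb = lkb_params(n = 0.38, m = 0.47, td50 = 41.0),
    spce_lkb = lkb_params(n = 0.36, m = 0.19, td50 = 57.7)
  )
}

# printed coefficient / odds-ratio pairings of the published logistic models
ref_odds_ratios <- function() {
  tibble::tibble(
    coefficient = c(0.073, 0.161, -1.858),
    odds_ratio = c(1.076, 1.174, 0.156)
  )
}

toy_dvh <- function() dvh(c(5, 15, 25), c(0.2, 0.3, 0.5))

random_dvh <- function(seed, target = NULL, heterogeneity = 6) {
  withr::with_seed(seed, {
    tgt <- target %||% runif(1, 5, 50)
    generate_dvh(tgt, heterogeneity, seed = NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
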