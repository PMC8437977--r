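#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a definitive
#' chemoradiotherapy oesophageal cancer cohort: 229 patients, mean heart
#' dose (MHD) with median 32.2 Gy on support 0.46-56.9 Gy, hypertension
#' prevalence 30.1%, and binary pericardial effusion outcomes drawn from a
#' declared truth model. The MHD marginal is a two-component truncated
#' log-normal mixture: a minor heart-sparing component (tumours high in
#' the thorax leave the heart largely out of field, which is how mean
#' heart doses below 1 Gy arise next to a 32 Gy median) and a dominant
#' component around the median, whose location is solved so the mixture
#' median hits the target. A single truncated log-normal pinned at the
#' printed median concentrates too much mass near it and over-predicts
#' the cohort event rates under the default truth models; the mixture
#' reproduces median, range and both printed incidences together.
#' Hypertension is drawn independently of MHD by default (the joint
#' distribution in the real cohort is unknown; a dependence knob exists
#' for sensitivity analyses).
#'
#' @param n_patients Cohort size, default 229.
#' @param mhd_median Target median MHD in Gy, default 32.2.
#' @param mhd_range MHD support in Gy, default `c(0.46, 56.9)`.
#' @param mhd_sdlog Log-scale spread of the dominant MHD component,
#'   default 0.25.
#' @param mhd_low_fraction Weight of the heart-sparing component, default
#'   0.20.
#' @param mhd_low_median Median MHD (Gy) of the heart-sparing component,
#'   default 5.
#' @param mhd_low_sdlog Log-scale spread of the heart-sparing component,
#'   default 1.0.
#' @param htn_prevalence Hypertension prevalence, default 0.301.
#' @param htn_mhd_dependence Log-odds shift of hypertension per
#'   standardised log-MHD; 0 (default) draws them independently.
#' @param truth_any Truth model for the any-grade endpoint
#'   ([logistic_model()] or [lkb_params()]); defaults to the MHD-based
#'   logistic model (intercept -2.513, 0.073 per Gy).
#' @param truth_sym Truth model for the symptomatic endpoint; defaults to
#'   the MHD-based probit model (m = 0.26, TD50 = 56.5 Gy).
#' @param dvh Generate a per-patient DVH list-column?
#' @param dvh_heterogeneity Scale (Gy) of the logistic fall-off of the
#'   generated cumulative DVHs; 0 gives uniform-dose patients. Default 8.
#' @param spce_subset Force symptomatic events to be a subset of any-grade
#'   events? Default `FALSE` (independent draws, endpoints analysed
#'   separately).
#' @param seed Default generation seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 229L,
                             mhd_median = 32.2,
                             mhd_range = c(0.46, 56.9),
                             mhd_sdlog = 0.25,
                             mhd_low_fraction = 0.20,
                             mhd_low_median = 5,
                             mhd_low_sdlog = 1.0,
                             htn_prevalence = 0.301,
                             htn_mhd_dependence = 0,
                             truth_any = logistic_model(-2.513, c(mhd = 0.073)),
                             truth_sym = lkb_params(1, 0.26, 56.5),
                             dvh = TRUE,
                             dvh_heterogeneity = 8,
                             spce_subset = FALSE,
                             seed = 20150137L) {
  if (htn_prevalence < 0 || htn_prevalence > 1) {
    abort_config("htn_prevalence must lie in [0, 1]")
  }
  if (any(mhd_range <= 0) || mhd_range[1] >= mhd_range[2]) {
    abort_config("mhd_range must be positive and increasing")
  }
  if (mhd_median <= mhd_range[1] || mhd_median >= mhd_range[2]) {
    abort_config("mhd_median must lie inside mhd_range")
  }
  if (dvh_heterogeneity < 0) abort_config("dvh_heterogeneity must be >= 0")
  if (mhd_low_fraction < 0 || mhd_low_fraction >= 1) {
    abort_config("mhd_low_fraction must lie in [0, 1)")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      mhd_median = mhd_median,
      mhd_range = mhd_range,
      mhd_sdlog = mhd_sdlog,
      mhd_low_fraction = mhd_low_fraction,
      mhd_low_median = mhd_low_median,
      mhd_low_sdlog = mhd_low_sdlog,
      htn_prevalence = htn_prevalence,
      htn_mhd_dependence = htn_mhd_dependence,
      truth_any = truth_any,
      truth_sym = truth_sym,
      dvh = isTRUE(dvh),
      dvh_heterogeneity = dvh_heterogeneity,
      spce_subset = isTRUE(spce_subset),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

trunc_lnorm_cdf <- function(x, meanlog, sdlog, range_gy) {
  pl <- plnorm(range_gy[1], meanlog, sdlog)
  pu <- plnorm(range_gy[2], meanlog, sdlog)
  (plnorm(x, meanlog, sdlog) - pl) / (pu - pl)
}

sample_truncated_lognormal <- function(n, meanlog, sdlog, range_gy) {
  pl <- plnorm(range_gy[1], meanlog, sdlog)
  pu <- plnorm(range_gy[2], meanlog, sdlog)
  qlnorm(pl + runif(n) * (pu - pl), meanlog, sdlog)
}

# location of the dominant component solved so the mixture's truncated
# median equals the target
solve_mhd_meanlog <- function(config) {
  w <- config$mhd_low_fraction
  mu1 <- log(config$mhd_low_median)
  target <- function(mu2) {
    w * trunc_lnorm_cdf(config$mhd_median, mu1, config$mhd_low_sdlog, config$mhd_range) +
      (1 - w) * trunc_lnorm_cdf(config$mhd_median, mu2, config$mhd_sdlog, config$mhd_range) -
      0.5
  }
  stats::uniroot(target,
    interval = log(config$mhd_median) + c(-2, 3), tol = 1e-10)$root
}

sample_mhd <- function(n, config) {
  meanlog <- solve_mhd_meanlog(config)
  low <- runif(n) < config$mhd_low_fraction
  out <- numeric(n)
  out[low] <- sample_truncated_lognormal(
    sum(low), log(config$mhd_low_median), config$mhd_low_sdlog, config$mhd_range)
  out[!low] <- sample_truncated_lognormal(
    sum(!low), meanlog, config$mhd_sdlog, config$mhd_range)
  out
}

#' Generate one synthetic heart DVH
#'
#' Emulates the cumulative DVH of a partially irradiated organ with a
#' logistic fall-off: V(D) = fraction of volume receiving at least D,
#' falling from 1 towards 0 around a location dose with scale
#' `heterogeneity` (Gy), truncated at a physical dose cap and renormalised.
#' The dose axis is then rescaled so the mean dose matches `target_mhd`
#' exactly (mean dose is linear in the dose axis). `heterogeneity = 0`
#' yields a single-bin uniform-dose DVH. With a seed the output is
#' bit-identical across calls; with `seed = NULL` the ambient RNG stream
#' is used (as when called from [generate_cohort()]).
#'
#' @param target_mhd Target mean dose in Gy, > 0.
#' @param heterogeneity Logistic fall-off scale in Gy, >= 0.
#' @param seed Integer seed or `NULL`.
#' @param bin_width Pre-scaling dose bin width in Gy, default 0.1.
#' @param physical_cap Dose cap (Gy) of the pre-scaling cumulative shape,
#'   default 66 (a conventional prescription-level maximum).
#' @param dose_cap Hard cap (Gy) on the scaled maximum dose, default 80; a
#'   target requiring scaling beyond it is a generation error.
#' @param jitter Randomly perturb the fall-off scale (factor in
#'   `[0.7, 1.3]`) so shapes vary across patients.
#' @return A [dvh()].
#' @export
generate_dvh <- function(target_mhd, heterogeneity, seed = NULL,
                         bin_width = 0.1, physical_cap = 66, dose_cap = 80,
                         jitter = TRUE) {
  if (target_mhd <= 0) abort_domain("target_mhd must be positive")
  if (heterogeneity < 0) abort_domain("heterogeneity must be non-negative")
  build <- function() {
    if (heterogeneity == 0) {
      return(dvh(target_mhd, 1, structure = "heart"))
    }
    s <- heterogeneity * (if (jitter) runif(1, 0.7, 1.3) else 1)
    d0 <- target_mhd
    edges <- seq(0, physical_cap, by = bin_width)
    v <- plogis((d0 - edges) / s)
    v <- (v - v[length(v)]) / (v[1] - v[length(v)]) # truncate + renormalise
    diff_vol <- -diff(v)
    mid <- (edges[-length(edges)] + edges[-1]) / 2
    d <- dvh(mid, pmax(diff_vol, 0), structure = "heart")
    scale <- target_mhd / mean_dose(d)
    if (scale * max(d$dose_gy) > dose_cap) {
      abort("target mean dose infeasible: scaled maximum dose exceeds the cap",
        class = "ntcppce_generation_error")
    }
    dvh(d$dose_gy * scale, d$volume_fraction, structure = "heart")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a synthetic cohort
#'
#' Draws per-patient mean heart dose, hypertension status, optionally a
#' DVH whose mean dose matches the drawn MHD, and binary pericardial
#' effusion outcomes as independent Bernoulli events with probability
#' given by the configured truth models. The configuration and seed are
#' recorded as attributes, so generation is fully reproducible.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to the one in `config`.
#' @return A cohort tibble with columns `patient_id`, `hypertension`,
#'   `mhd`, optionally `dvh` (list-column), `p_any`, `p_sym`,
#'   `outcome_any_grade`, `outcome_symptomatic`, and attributes
#'   `synthetic_seed` and `synthetic_config`.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  cohort <- withr::with_seed(seed, {
    mhd <- sample_mhd(n, config)
    eta_htn <- qlogis(config$htn_prevalence) +
      config$htn_mhd_dependence * scale(log(mhd))[, 1]
    htn <- rbinom(n, 1, plogis(eta_htn))
    out <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      hypertension = htn,
      mhd = mhd
    )
    if (config$dvh) {
      out$dvh <- purrr::map(mhd, function(d) {
        generate_dvh(d, config$dvh_heterogeneity, seed = NULL)
      })
    }
    p_any <- predict_ntcp(config$truth_any, out)
    p_sym <- predict_ntcp(config$truth_sym, out)
    out$p_any <- p_any
    out$p_sym <- p_sym
    out$outcome_any_grade <- rbinom(n, 1, p_any)
    out$outcome_symptomatic <- rbinom(n, 1, p_sym)
    if (config$spce_subset) {
      out$outcome_symptomatic <- out$outcome_symptomatic * out$outcome_any_grade
    }
    out
  })
  attr(cohort, "synthetic_seed") <- as.integer(seed)
  attr(cohort, "synthetic_config") <- config
  attr(cohort, "htn_mhd_independent") <- config$htn_mhd_dependence == 0
  cohort
}

#' Read or write a cohort table CSV
#'
#' One row per patient with the covariates, the mean heart dose, and the
#' binary outcomes; the generation seed (if any) is echoed in a header
#' comment. The DVH list-column is not serialised here — use
#' [write_dvh()] per structure/patient for that.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  tab <- dplyr::select(cohort, -dplyr::any_of("dvh"))
  seed <- attr(cohort, "synthetic_seed")
  header <- if (!is.null(seed)) sprintf("# synthetic_seed: %d", seed) else "# cohort"
  writeLines(header, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (anyDuplicated(tab$patient_id)) abort_malformed("duplicate patient_id values")
  tab
}
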