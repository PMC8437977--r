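test_that("gEUD reproduces hand values and its limiting behaviour", {
  uni <- dvh(35, 1)
  for (n in c(0.1, 0.5, 1, 2)) expect_equal(geud(uni, n), 35)

  two <- dvh(c(10, 40), c(0.5, 0.5))
  expect_equal(geud(two, 0.5), sqrt(0.5 * 10^2 + 0.5 * 40^2), tolerance = 1e-9)
  expect_equal(geud(two, 0.5), 29.1548, tolerance = 1e-4)

  # n = 1 is the mean dose, to machine precision on identical binning
  for (seed in 1:5) {
    r <- random_dvh(seed)
    expect_equal(geud(r, 1), mean_dose(r), tolerance = 1e-9)
    # gEUD decreases with n for a heterogeneous dose distribution
    g <- geud(r, c(0.05, 0.3, 1, 2))
    expect_true(all(diff(g) < 0))
  }
  # small n approaches the maximum dose: at n = 0.05 the gEUD of a coarse
  # DVH falls inside its top occupied bin
  coarse <- dvh(seq(5, 45, 10), c(0.1, 0.2, 0.3, 0.25, 0.15))
  expect_gte(geud(coarse, 0.05), 40)
  expect_lte(geud(coarse, 0.05), 45 + 5)
  expect_error(geud(two, 0), class = "ntcppce_domain_error")
  expect_error(geud(two, -1), class = "ntcppce_domain_error")
})

test_that("gEUD ignores zero-dose bins and is non-decreasing in bin dose", {
  with_zero <- dvh(c(0, 10, 20), c(0.5, 0.25, 0.25))
  # zero-dose bins contribute nothing to the power sum but keep their weight
  expect_equal(geud(with_zero, 1), mean_dose(with_zero), tolerance = 1e-9)
  expect_equal(geud(with_zero, 0.5), sqrt(0.25 * 100 + 0.25 * 400), tolerance = 1e-9)
  shifted <- dvh(c(0, 10, 20) + 2, c(0.5, 0.25, 0.25))
  for (n in c(0.2, 1)) expect_gt(geud(shifted, n), geud(with_zero, n))
})

test_that("probit NTCP matches the published operating points", {
  m <- ref_models()
  expect_equal(probit_ntcp(34.3, m$apce_probit_mhd), 0.5)
  expect_equal(round(probit_ntcp(30, m$apce_probit_mhd), 2), 0.43)
  expect_equal(round(probit_ntcp(40, m$spce_probit_mhd), 2), 0.13)
  # strictly monotone in dose, bounded in (0, 1)
  p <- probit_ntcp(seq(0, 80, by = 0.5), m$apce_lkb)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("logistic NTCP matches the published operating points", {
  m <- ref_models()$apce_logistic
  expect_equal(round(logistic_ntcp(c(mhd = 30), m), 2), 0.42)
  expect_equal(round(logistic_ntcp(c(mhd = 10), m), 2), 0.14)
  expect_equal(logistic_ntcp(c(mhd = 2.513 / 0.073), m), 0.5)
  # data-frame input is vectorised over patients
  df <- tibble::tibble(mhd = c(10, 30))
  expect_equal(round(logistic_ntcp(df, m), 2), c(0.14, 0.42))
  expect_error(logistic_ntcp(c(dose = 30), m), class = "ntcppce_contract_error")
})

test_that("tolerance-dose inversion is the inverse of the forward model", {
  m <- ref_models()
  expect_equal(invert_td(m$apce_lkb, 0.5), 41.0)
  expect_equal(round(invert_td(m$apce_logistic, 0.25), 1), 19.4)
  # the MHD-based any-grade model never reaches 5% at a positive dose
  expect_true(is.na(invert_td(m$apce_probit_mhd, 0.05)))

  xs <- seq(0.02, 0.98, by = 0.04)
  for (mod in list(m$apce_probit_mhd, m$spce_lkb)) {
    td <- invert_td(mod, xs)
    ok <- !is.na(td)
    expect_equal(probit_ntcp(td[ok], mod), xs[ok], tolerance = 1e-9)
  }
  td <- invert_td(m$apce_logistic, xs)
  ok <- !is.na(td)
  expect_equal(
    vapply(td[ok], function(d) logistic_ntcp(c(mhd = d), m$apce_logistic), numeric(1)),
    xs[ok],
    tolerance = 1e-9
  )
})

test_that("multivariable logistic inversion requires a covariate profile", {
  m <- ref_models()$spce_logistic
  expect_error(invert_td(m, 0.5), class = "ntcppce_contract_error")
  td0 <- invert_td(m, 0.5, dose_feature = "mhd", profile = c(hypertension = 0))
  td1 <- invert_td(m, 0.5, dose_feature = "mhd", profile = c(hypertension = 1))
  # the negative hypertension coefficient shifts the curve to higher doses
  expect_gt(td1, td0)
  expect_equal(
    logistic_ntcp(c(mhd = td1, hypertension = 1), m), 0.5,
    tolerance = 1e-9
  )
})

test_that("coefficient of determination follows its defining sum of squares", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_error(r_squared(c(2, 2, 2), y), class = "ntcppce_domain_error")
  expect_error(r_squared(y, c(1, 2)), class = "ntcppce_contract_error")
})

test_that("model parameter JSON files round-trip", {
  m <- ref_models()
  p1 <- withr::local_tempfile(fileext = ".json")
  write_model(m$apce_lkb, p1)
  back <- read_model(p1)
  expect_s3_class(back, "lkb_params")
  expect_equal(back$td50, 41.0)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m$spce_logistic, p2)
  back2 <- read_model(p2)
  expect_equal(back2$coefficients, m$spce_logistic$coefficients)
})
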