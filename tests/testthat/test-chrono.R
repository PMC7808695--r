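identity_curve <- function(span = c(0, 6000)) {
  simulate_calcurve(seed = 1, span_calbp = span, wiggle_sd = 0,
                    sigma_curve = 1e-6)
}

test_that("Gaussian date on the identity curve calibrates to its 2-sigma range", {
  cal <- calibrate(radiocarbon_date(3000, 30), identity_curve())
  expect_equal(nrow(cal$hpd), 1L)
  expect_equal(cal$hpd$cal_bp_old, 3060)
  expect_equal(cal$hpd$cal_bp_young, 2940)
  expect_true(cal$hpd$mass >= 0.954 && cal$hpd$mass <= 0.97)
  expect_equal(sum(cal$density), 1)
  expect_equal(cal$median_cal_bp, 3000)
})

test_that("constant curve uncertainty widens the range to sqrt(sigma^2 + s^2)", {
  cv <- simulate_calcurve(seed = 1, span_calbp = c(0, 6000), wiggle_sd = 0,
                          sigma_curve = 40)
  cal <- calibrate(radiocarbon_date(3000, 30), cv)
  s_eff <- sqrt(30^2 + 40^2)
  expect_lt(abs(cal$hpd$cal_bp_old - (3000 + 2 * s_eff)), 3)
  expect_lt(abs(cal$hpd$cal_bp_young - (3000 - 2 * s_eff)), 3)
})

test_that("cal BCE conversion uses the 1950 datum with the older bound first", {
  cal <- calibrate(radiocarbon_date(4500, 25), identity_curve())
  expect_equal(cal$hpd_bce$bce_old, cal$hpd$cal_bp_old - 1950)
  expect_true(all(cal$hpd_bce$bce_old >= cal$hpd_bce$bce_young))
})

test_that("posterior mass in HPD intervals stays within [0.954, 0.97] on wiggly curves", {
  cv <- simulate_calcurve(seed = 9, span_calbp = c(2000, 6000),
                          wiggle_sd = 60, sigma_curve = 15)
  for (m in c(3000, 3500, 4200, 5000)) {
    cal <- calibrate(radiocarbon_date(m, 30), cv)
    total <- sum(cal$hpd$mass)
    expect_gte(total, 0.954)
    expect_lte(total, 0.97)
  }
})

test_that("a monotone curve yields one interval; wiggles can split it", {
  mono <- calibrate(radiocarbon_date(3300, 30), identity_curve())
  expect_equal(nrow(mono$hpd), 1L)
  cv <- simulate_calcurve(seed = 9, span_calbp = c(2000, 6000),
                          wiggle_sd = 60, sigma_curve = 15)
  n_int <- vapply(seq(2500, 5500, by = 100), function(m) {
    nrow(calibrate(radiocarbon_date(m, 30), cv)$hpd)
  }, numeric(1))
  expect_gt(max(n_int), 1)
})

test_that("dates outside the curve span are rejected", {
  expect_error(calibrate(radiocarbon_date(9000, 30), identity_curve()),
               "outside curve span")
})

test_that("replicate pooling follows inverse-variance weighting with a chi2 gate", {
  two <- combine_dates(list(radiocarbon_date(3900, 30),
                            radiocarbon_date(3854, 30)))
  expect_equal(round(two$date$uncal_bp), 3877)
  expect_equal(round(two$date$sigma), 21)
  expect_true(two$pass)

  same <- combine_dates(list(radiocarbon_date(3000, 40),
                             radiocarbon_date(3000, 40)))
  expect_equal(same$date$uncal_bp, 3000)
  expect_equal(same$date$sigma, 40 / sqrt(2))
  expect_equal(same$chi2, 0)

  apart <- combine_dates(list(radiocarbon_date(3000, 30),
                              radiocarbon_date(3300, 30)))
  expect_false(apart$pass)

  expect_error(combine_dates(list(radiocarbon_date(3000, 30))), "at least 2")

  perm <- combine_dates(list(radiocarbon_date(3854, 30),
                             radiocarbon_date(3900, 30)))
  expect_equal(perm$date$uncal_bp, two$date$uncal_bp)
  expect_equal(perm$chi2, two$chi2)
})

test_that("marine fraction interpolates linearly between the diet endpoints", {
  expect_equal(marine_fraction(-22), 0)
  expect_equal(marine_fraction(-10), 1)
  expect_equal(marine_fraction(-16), 0.5)
  expect_equal(marine_fraction(-25), 0)   # clamped
  expect_equal(marine_fraction(-5), 1)
  expect_error(diet_model(delta13c_terrestrial = -10, delta13c_marine = -22),
               "endpoint")
})

test_that("reservoir correction shifts ages by alpha * R and propagates error", {
  d <- radiocarbon_date(3950, 31)
  expect_equal(reservoir_correct(d, 0)$uncal_bp, 3950)
  expect_equal(reservoir_correct(d, 0)$sigma, 31)
  r02 <- reservoir_correct(d, 0.2)
  expect_equal(d$uncal_bp - r02$uncal_bp, 54.6)
  full <- reservoir_correct(d, 1)
  expect_equal(full$uncal_bp, 3950 - 273)
  expect_equal(full$sigma, sqrt(31^2 + 18^2))
  expect_true(full$reservoir_corrected)
  expect_error(reservoir_correct(d, 1.2), "alpha")
})

test_that("the calibrated median moves young-ward by alpha * R on the identity curve", {
  d <- radiocarbon_date(4000, 30)
  alpha <- 0.2
  base <- calibrate(d, identity_curve())
  corr <- calibrate(reservoir_correct(d, alpha), identity_curve())
  expect_lt(abs((base$median_cal_bp - corr$median_cal_bp) - 54.6), 1.5)
})
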