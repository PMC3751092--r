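test_that("MCAR amputes an exact count and nothing else", {
  d <- fixture_dataset(4000)
  a <- impose_mcar(d, 0.15, seed = 41)
  expect_equal(sum(is.na(a$wc2)), round(0.15 * nrow(d)))
  expect_identical(a[setdiff(names(a), "wc2")], d[setdiff(names(d), "wc2")])
  expect_identical(a$wc2[!is.na(a$wc2)], d$wc2[!is.na(a$wc2)])
  expect_identical(impose_mcar(d, 0), d)
  expect_error(impose_mcar(d, 1), "prop")
})

test_that("MCAR selection is independent of the data", {
  d <- fixture_dataset(2000)
  set.seed(42)
  diffs <- replicate(300, {
    a <- impose_mcar(d, 0.3)
    mean(d$wc2[is.na(a$wc2)]) - mean(d$wc2[!is.na(a$wc2)])
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("cdmar_probability evaluates the logistic model", {
  d <- fixture_dataset(1000)
  null_model <- missingness_model("standard")
  null_model$gamma <- 0 * null_model$gamma
  null_model$gamma0 <- 0
  expect_equal(cdmar_probability(d, null_model), rep(0.5, nrow(d)))
  null_model$gamma0 <- qlogis(0.3)
  expect_equal(cdmar_probability(d, null_model), rep(0.3, nrow(d)))

  # fully specified reference row, evaluated term-by-term by hand:
  # male, age 60, WC1 = 90 cm, reference level of every categorical
  ref <- constant_cohort(1, age = 60, female = 0L)
  ref$wc1 <- 90
  m <- missingness_model("standard", gamma0 = -2)
  hand <- plogis(-2 + 9 * log(1.10) + 60 * log(1.06))
  expect_equal(cdmar_probability(ref, m), hand)
  # uncalibrated intercept is an error
  expect_error(cdmar_probability(ref, missingness_model("standard")),
               "calibrated")
})

test_that("intercept calibration matches closed forms and its contract", {
  d <- fixture_dataset(4000)
  flat <- missingness_model("standard")
  flat$gamma <- 0 * flat$gamma
  expect_equal(calibrate_intercept(d, flat, 0.3), qlogis(0.3),
               tolerance = 1e-5)
  expect_equal(calibrate_intercept(d, flat, 0.5), 0, tolerance = 1e-5)
  for (prop in c(0.15, 0.30, 0.50)) {
    m <- missingness_model("standard")
    g0 <- calibrate_intercept(d, m, prop, tol = 1e-6)
    m$gamma0 <- g0
    expect_lt(abs(mean(cdmar_probability(d, m)) - prop), 1e-6)
  }
  expect_error(calibrate_intercept(d, flat, 0), "strictly")
})

test_that("covariate-dependent amputation hits its expected proportion", {
  cov <- generate_covariates(41476, seed = 43)
  d <- simulate_waist(cov, exposure_params(), seed = 44)
  a <- impose_cdmar(d, missingness_model("enhanced"), 0.5, seed = 45)
  expect_lt(abs(mean(is.na(a$wc2)) - 0.5), 3 * sqrt(0.25 / nrow(d)))
  # missingness leans towards high-WC1 rows when the WC1 coefficient is large
  strong <- missingness_model("standard")
  strong$gamma["wc1_10cm"] <- 5
  b <- impose_cdmar(d, strong, 0.3, seed = 46)
  expect_gt(cor(is.na(b$wc2), d$wc1, method = "spearman"), 0)
})

test_that("amputation log-odds are recovered by logistic regression", {
  cov <- generate_covariates(80000, seed = 47)
  d <- simulate_waist(cov, exposure_params(), seed = 48)
  m <- missingness_model("standard")
  a <- impose_cdmar(d, m, 0.3, seed = 49)
  X <- misurvsim:::covariate_design(d)
  df <- data.frame(miss = as.integer(is.na(a$wc2)), wc1_10cm = d$wc1 / 10,
                   X[, setdiff(names(m$gamma), "wc1_10cm")])
  fit <- glm(miss ~ ., family = binomial, data = df)
  est <- coef(fit)[names(m$gamma)]
  se <- sqrt(diag(vcov(fit)))[names(m$gamma)]
  expect_true(all(abs(est - m$gamma) < 3 * se))
})

test_that("enhanced scenario squares the standard odds ratios", {
  tab <- mar_scenario_table()
  printed_enhanced <- c(1.21, 1.12, 1.21, 0.52, 0.19, 1.32, 2.92,
                        0.59, 0.44, 0.72, 1.35, 3.24, 0.86, 0.98, 0.83)
  expect_equal(round(tab$or_standard^2, 2), printed_enhanced)
  expect_equal(tab$or_enhanced, printed_enhanced)
  m1 <- missingness_model("standard", gamma0 = -1)
  m2 <- enhance_scenario(m1)
  expect_equal(m2$gamma, 2 * m1$gamma)
  expect_true(is.na(m2$gamma0))
  # OR 1 is a fixed point of the enhancement
  unit <- m1; unit$gamma["physical_moderate"] <- 0
  expect_equal(enhance_scenario(unit)$gamma[["physical_moderate"]], 0)
})
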