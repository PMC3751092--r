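test_that("Nelson-Aalen increments match hand-computed risk sets", {
  d <- data.frame(entry_age = c(0, 0, 0), exit_age = c(1, 2, 3),
                  event = c(1, 0, 1))
  expect_equal(nelson_aalen(d), c(1/3, 1/3, 1/3 + 1))
  # late entry shrinks the risk set at the last event age to 2
  d2 <- rbind(d, data.frame(entry_age = 2.5, exit_age = 3, event = 0))
  expect_equal(nelson_aalen(d2), c(1/3, 1/3, 1/3 + 1/2, 1/3 + 1/2))
  # no events at all
  d3 <- transform(d, event = 0)
  expect_equal(nelson_aalen(d3), c(0, 0, 0))
  expect_error(nelson_aalen(data.frame()), "no survival records")
  expect_error(nelson_aalen(data.frame(entry_age = 1, exit_age = 1,
                                       event = 1)), "strictly")
})

test_that("Nelson-Aalen agrees with the survival package on simulated data", {
  d <- fixture_dataset(4000)
  H <- nelson_aalen(d)
  sf <- survival::survfit(
    survival::coxph(survival::Surv(entry_age, exit_age, event) ~ 1,
                    data = d, ties = "breslow",
                    control = survival::coxph.control(timefix = FALSE)),
    type = "aalen")
  Href <- stats::stepfun(sf$time, c(0, sf$cumhaz))(d$exit_age)
  expect_equal(H, Href, tolerance = 1e-8)
})

test_that("imputation draws reproduce the closed-form posterior predictive", {
  set.seed(51)
  n_obs <- 500
  X_obs <- cbind(intercept = 1, x1 = rnorm(n_obs), x2 = runif(n_obs))
  y_obs <- drop(X_obs %*% c(2, 1.5, -0.7)) + rnorm(n_obs, sd = 2)
  x_new <- rbind(c(1, 0.3, 0.6))
  colnames(x_new) <- colnames(X_obs)
  draws <- replicate(4000, draw_imputation(y_obs, X_obs, x_new))
  # oracle: under the noninformative prior the predictive at x is a
  # location-scale t with df = n - k
  qx <- qr(X_obs)
  beta_hat <- qr.coef(qx, y_obs)
  df <- n_obs - ncol(X_obs)
  s2 <- sum(qr.resid(qx, y_obs)^2) / df
  lever <- drop(x_new %*% solve(crossprod(X_obs)) %*% t(x_new))
  pred_mean <- drop(x_new %*% beta_hat)
  pred_var <- s2 * (1 + lever) * df / (df - 2)
  expect_lt(abs(mean(draws) - pred_mean),
            4 * sqrt(pred_var / length(draws)))
  expect_lt(abs(var(draws) - pred_var), 4 * pred_var * sqrt(2 / length(draws)))
})

test_that("degenerate imputation cases behave as contracts state", {
  set.seed(52)
  X <- cbind(intercept = 1, x = rnorm(30))
  # exact linear relationship: RSS = 0, draws are the deterministic fit
  y <- drop(X %*% c(1, 2))
  x_new <- rbind(c(1, 5), c(1, -3)); colnames(x_new) <- colnames(X)
  expect_equal(draw_imputation(y, X, x_new), c(11, -5))
  # zero missing rows
  expect_length(draw_imputation(y, X, X[0, , drop = FALSE]), 0)
  # rank deficiency names the collinear column
  X2 <- cbind(X, x_dup = X[, "x"])
  expect_error(draw_imputation(y + rnorm(30), X2, x_new), "x_dup")
})

test_that("impute returns m completed tables agreeing on observed rows", {
  d <- impose_mcar(fixture_dataset(3000), 0.3, seed = 53)
  obs <- !is.na(d$wc2)
  comp <- impute(d, m = 5, seed = 54)
  expect_length(comp, 5)
  for (ci in comp) {
    expect_false(anyNA(ci$wc2))
    expect_identical(ci$wc2[obs], d$wc2[obs])
    expect_identical(ci[setdiff(names(ci), "wc2")],
                     d[setdiff(names(d), "wc2")])
  }
  # no two imputations identical on the missing rows
  expect_false(identical(comp[[1]]$wc2[!obs], comp[[2]]$wc2[!obs]))
  # seeded reproducibility
  comp2 <- impute(d, m = 5, seed = 54)
  expect_identical(comp, comp2)
  # table with no missing values: m identical copies
  full <- fixture_dataset(3000)
  expect_identical(unique(impute(full, m = 2, seed = 55)), list(full))
  expect_error(impute(d, m = 1), "at least 2")
})

test_that("MCAR imputation preserves the exposure mean", {
  full <- fixture_dataset(4000)
  d <- impose_mcar(full, 0.5, seed = 56)
  comp <- impute(d, m = 50, seed = 57)
  miss <- is.na(d$wc2)
  imp_means <- vapply(comp, function(ci) mean(ci$wc2[miss]), numeric(1))
  true_mean <- mean(full$wc2[miss])
  expect_lt(abs(mean(imp_means) - true_mean),
            3 * sd(full$wc2) / sqrt(sum(miss)))
})

test_that("Rubin's rules match hand-computed cases", {
  # worked two-imputation case
  p <- rubin_pool(c(0, 2), c(1, 1))
  expect_equal(p$qbar, 1); expect_equal(p$W, 1); expect_equal(p$B, 2)
  expect_equal(p$T, 4); expect_equal(p$se, 2); expect_equal(p$df, 16 / 9)
  expect_equal(p$ci95, 1 + c(-1, 1) * qt(0.975, 16 / 9) * 2)
  # identical estimates: B = 0, T = W, normal interval
  p2 <- rubin_pool(c(1, 1, 1), c(4, 4, 4))
  expect_equal(p2$qbar, 1); expect_equal(p2$B, 0); expect_equal(p2$T, 4)
  expect_equal(p2$se, 2); expect_identical(p2$df, Inf)
  expect_equal(p2$ci95, 1 + c(-1, 1) * qnorm(0.975) * 2)
  # permutation invariance
  e <- c(0.1, 0.5, 0.3, 0.2); v <- c(1, 2, 1.5, 1.2)
  perm <- c(3, 1, 4, 2)
  expect_equal(rubin_pool(e, v)[c("qbar", "T", "df")],
               rubin_pool(e[perm], v[perm])[c("qbar", "T", "df")])
  # T >= W always, equality iff estimates identical
  expect_gte(rubin_pool(e, v)$T, rubin_pool(e, v)$W)
  expect_error(rubin_pool(1, 1), "at least 2")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "positive")
})

test_that("MI under MCAR converges to the complete-data estimate", {
  set.seed(58)
  diffs <- replicate(10, {
    cfg <- sim_config("desk", n = 4000, m = 20)
    full <- sim_dataset(cfg)
    d <- impose_mcar(full, 0.5)
    mi <- mi_estimate(d, "a", m = 20)
    mi$qbar - fit_model_a(full)$target_loghr
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})
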