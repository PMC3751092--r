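# Multiple imputation engine. Missing wave-2 waist values are drawn from a
# proper Bayesian normal linear regression fitted to the observed rows: the
# residual variance is drawn from its scaled inverse-chi-square posterior,
# the coefficients from their normal posterior given that variance, and the
# imputations add residual noise, so both sources of uncertainty propagate
# into the between-imputation variance. The imputation model contains the
# analysis covariates, the lifestyle auxiliaries, the cancer-vs-censored
# event indicator and the Nelson-Aalen cumulative hazard at exit.

#' Nelson-Aalen cumulative hazard at each subject's exit age
#'
#' Computes `H(t) = sum over event ages a <= t of d(a) / n(a)` with the
#' left-truncation-aware risk set `n(a) = #(entry < a <= exit)`, and
#' returns `H(exit_age_i)` for every subject. Used as a survival-aware
#' predictor in the imputation model, on the same (age) clock as the
#' analysis model.
#'
#' @param data Table with `entry_age`, `exit_age`, `event` columns (or
#'   vectors via `entry`, `exit`, `event`).
#' @param entry,exit,event Optional explicit vectors overriding `data`.
#' @return Numeric vector of per-subject cumulative hazards.
#' @export
#' @examples
#' d <- data.frame(entry_age = c(0, 0, 0), exit_age = c(1, 2, 3),
#'                 event = c(1, 0, 1))
#' nelson_aalen(d)  # 1/3, 1/3, 4/3
nelson_aalen <- function(data = NULL, entry = data$entry_age,
                         exit = data$exit_age, event = data$event) {
  if (is.null(entry) || length(entry) == 0L) stop("no survival records")
  stopifnot(length(exit) == length(entry), length(event) == length(entry))
  if (any(exit <= entry)) stop("exit must be strictly after entry")
  ev_times <- sort(unique(exit[event == 1]))
  if (length(ev_times) == 0L) return(numeric(length(entry)))
  d <- vapply(ev_times, function(a) sum(exit == a & event == 1), numeric(1))
  se <- sort(exit); sn <- sort(entry)
  n_at_risk <- findInterval(ev_times, sn, left.open = TRUE) -
    findInterval(ev_times, se, left.open = TRUE)
  cumhaz <- cumsum(d / n_at_risk)
  idx <- findInterval(exit, ev_times)
  c(0, cumhaz)[idx + 1L]
}

# Build the imputation design: response wc2, predictors per the design
# options. Returns y, X (with intercept), and the missingness indicator.
imputation_design <- function(data, use_event_indicator = TRUE,
                              use_nelson_aalen = TRUE,
                              use_lifestyle_aux = TRUE) {
  need <- c("wc1", "wc2", "entry_age", "exit_age", "event")
  if (!all(need %in% names(data)))
    stop("table lacks imputation-design columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  Z <- covariate_design(data)
  keep <- c("age", "female", "education_secondary", "education_tertiary",
            "cob_uk", "cob_mediterranean")
  if (use_lifestyle_aux)
    keep <- c(keep, "smoking_former", "smoking_current", "physical_low",
              "physical_moderate", "physical_high", "alcohol_low",
              "alcohol_moderate", "alcohol_high")
  X <- cbind(intercept = 1, wc1 = data$wc1, Z[, keep, drop = FALSE])
  if (use_event_indicator) X <- cbind(X, event = data$event)
  if (use_nelson_aalen) X <- cbind(X, nelson_aalen = nelson_aalen(data))
  list(y = data$wc2, X = X, miss = is.na(data$wc2))
}

#' One proper draw of imputed values from a normal regression model
#'
#' Fits `y_obs ~ X_obs` by least squares, draws the residual variance from
#' `RSS / chisq(n_obs - k)`, the coefficient vector from its conditional
#' normal posterior, and returns `X_mis beta* + noise`. This is the proper
#' Bayesian imputation under the conventional noninformative prior on
#' `(beta, log sigma)`.
#'
#' @param y_obs Observed responses.
#' @param X_obs Design matrix for observed rows (include the intercept).
#' @param X_mis Design matrix for rows to impute (same columns).
#' @return Numeric vector of imputed values, one per row of `X_mis`
#'   (length zero when `X_mis` has no rows).
#' @export
draw_imputation <- function(y_obs, X_obs, X_mis) {
  X_obs <- as.matrix(X_obs)
  n_obs <- nrow(X_obs); k <- ncol(X_obs)
  if (n_obs <= k + 1) stop("too few observed rows to fit the imputation model")
  qx <- qr(X_obs)
  if (qx$rank < k) {
    bad <- colnames(X_obs)[qx$pivot[(qx$rank + 1L):k]]
    stop("imputation design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta_hat <- qr.coef(qx, y_obs)
  rss <- sum(qr.resid(qx, y_obs)^2)
  sigma2_star <- if (rss == 0) 0 else rss / rchisq(1L, df = n_obs - k)
  beta_star <- beta_hat +
    sqrt(sigma2_star) * backsolve(qr.R(qx), rnorm(k))[order(qx$pivot)]
  n_mis <- nrow(X_mis)
  if (is.null(n_mis) || n_mis == 0L) return(numeric(0))
  drop(as.matrix(X_mis) %*% beta_star) +
    rnorm(n_mis, 0, sqrt(sigma2_star))
}

#' Multiply impute missing wave-2 waist circumference
#'
#' Produces `m` completed copies of the table. Observed `wc2` values are
#' identical in every copy; missing values are replaced by independent
#' proper draws ([draw_imputation()]). With an integer `seed` (or when the
#' active generator is L'Ecuyer-CMRG, as inside [run_cell()] replicates),
#' each imputation runs under its own RNG sub-stream, so imputations are
#' independent and the whole set is reproducible from the seed.
#'
#' @param data Amputed table (covariates, `wc1`, possibly-missing `wc2`,
#'   survival columns).
#' @param m Number of imputations, at least 2.
#' @param seed Optional integer seed.
#' @param use_event_indicator,use_nelson_aalen,use_lifestyle_aux Imputation
#'   design switches (all on by default).
#' @return A list of `m` completed data.frames.
#' @export
impute <- function(data, m = 20, seed = NULL, use_event_indicator = TRUE,
                   use_nelson_aalen = TRUE, use_lifestyle_aux = TRUE) {
  if (m < 2) stop("m must be at least 2")
  des <- imputation_design(data, use_event_indicator, use_nelson_aalen,
                           use_lifestyle_aux)
  X_obs <- des$X[!des$miss, , drop = FALSE]
  y_obs <- des$y[!des$miss]
  X_mis <- des$X[des$miss, , drop = FALSE]
  run <- function() {
    out <- vector("list", m)
    env <- globalenv()
    base <- if (rng_is_lecuyer()) get(".Random.seed", envir = env) else NULL
    for (j in seq_len(m)) {
      if (!is.null(base)) {
        base <- parallel::nextRNGSubStream(base)
        assign(".Random.seed", base, envir = env)
      }
      completed <- data
      if (any(des$miss))
        completed$wc2[des$miss] <- draw_imputation(y_obs, X_obs, X_mis)
      out[[j]] <- completed
    }
    out
  }
  if (is.null(seed)) return(run())
  env <- globalenv()
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(restore_rng(old_seed, old_kind), add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(seed))
  run()
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Per-imputation point estimates (log hazard ratios).
#' @param variances Per-imputation squared standard errors.
#' @return A list of class `pooled_result`: `qbar` (pooled estimate), `W`
#'   (within-imputation variance), `B` (between), `T = W + (1 + 1/m) B`,
#'   `se = sqrt(T)`, small-sample `df` (infinite when `B = 0`), and the
#'   t-based `ci95`.
#' @export
#' @examples
#' rubin_pool(c(0, 2), c(1, 1))  # qbar 1, T 4, se 2, df 16/9
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("at least 2 imputations are required to pool")
  if (length(variances) != m) stop("estimates/variances length mismatch")
  if (any(variances <= 0)) stop("variances must be positive")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B == 0) {
    df <- Inf
    half <- qnorm(0.975) * sqrt(Tv)
  } else {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    half <- qt(0.975, df) * sqrt(Tv)
  }
  structure(list(qbar = qbar, W = W, B = B, T = Tv, se = sqrt(Tv), df = df,
                 ci95 = c(qbar - half, qbar + half), m = m),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate %.4f (se %.4f), m = %d, df = %.1f\n  95%% CI [%.4f, %.4f]  W = %.5f  B = %.5f\n",
    x$qbar, x$se, x$m, x$df, x$ci95[1], x$ci95[2], x$W, x$B))
  invisible(x)
}
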