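# Amputation: deliberate imposition of missingness on the wave-2 exposure.
# MCAR removes an exact-count simple random subset. The covariate-dependent
# MAR scenarios follow a logistic model in wave-1 waist circumference (per
# 10 cm), age and the categorical covariates, with the intercept calibrated
# by bisection so the expected missingness proportion hits its target; the
# enhanced scenario doubles every log odds ratio of the standard one.

# Odds ratios for missingness, standard covariate-dependent MAR scenario.
CDMAR_OR_STANDARD <- c(
  wc1_10cm = 1.10, age = 1.06, female = 1.10,
  education_secondary = 0.72, education_tertiary = 0.44,
  cob_uk = 1.15, cob_mediterranean = 1.71,
  alcohol_low = 0.77, alcohol_moderate = 0.66, alcohol_high = 0.85,
  smoking_former = 1.16, smoking_current = 1.80,
  physical_low = 0.93, physical_moderate = 0.99, physical_high = 0.91
)

#' Odds-ratio table for the covariate-dependent MAR scenarios
#'
#' @return A data.frame with one row per missingness predictor and the
#'   standard-scenario and enhanced-scenario odds ratios (the latter are
#'   the squared standard ones, shown at 2 decimal places).
#' @export
mar_scenario_table <- function() {
  data.frame(
    predictor = names(CDMAR_OR_STANDARD),
    or_standard = unname(CDMAR_OR_STANDARD),
    or_enhanced = round(unname(CDMAR_OR_STANDARD)^2, 2)
  )
}

#' Construct a covariate-dependent MAR missingness model
#'
#' @param scenario `"standard"` (odds ratios as observed for wave-2
#'   non-attendance) or `"enhanced"` (log odds ratios doubled).
#' @param gamma0 Logistic intercept; `NA` means "not yet calibrated"
#'   ([impose_cdmar()] calibrates it to the target proportion).
#' @param or Optional named odds-ratio override (standard scenario scale).
#' @return A list of class `missingness_model` with `gamma0` and the
#'   log-odds coefficient vector `gamma`.
#' @export
missingness_model <- function(scenario = c("standard", "enhanced"),
                              gamma0 = NA_real_, or = NULL) {
  scenario <- match.arg(scenario)
  or <- or %||% CDMAR_OR_STANDARD
  if (!identical(sort(names(or)), sort(names(CDMAR_OR_STANDARD))))
    stop("odds-ratio override must name exactly the 15 missingness ",
         "predictors")
  gamma <- log(or[names(CDMAR_OR_STANDARD)])
  if (scenario == "enhanced") gamma <- 2 * gamma
  structure(list(gamma0 = gamma0, gamma = gamma, scenario = scenario),
            class = "missingness_model")
}

#' Double the log odds ratios of a missingness model
#'
#' Turns a standard-scenario model into the enhanced scenario by doubling
#' every non-intercept coefficient (equivalently squaring the odds ratios);
#' the intercept is reset to uncalibrated since the target proportion must
#' be re-attained.
#'
#' @param model A `missingness_model`.
#' @return The enhanced `missingness_model`.
#' @export
enhance_scenario <- function(model) {
  stopifnot(inherits(model, "missingness_model"))
  structure(list(gamma0 = NA_real_, gamma = 2 * model$gamma,
                 scenario = "enhanced"),
            class = "missingness_model")
}

# Linear predictor of the missingness model, excluding the intercept.
cdmar_eta <- function(data, model) {
  if (!"wc1" %in% names(data)) stop("data must contain wc1")
  X <- covariate_design(data)
  g <- model$gamma
  drop(g[["wc1_10cm"]] * data$wc1 / 10 +
         X[, setdiff(names(g), "wc1_10cm"), drop = FALSE] %*%
           g[setdiff(names(g), "wc1_10cm")])
}

#' Per-subject probability of a missing wave-2 measurement
#'
#' Inverse-logit of the missingness model's linear predictor. The wave-1
#' waist coefficient applies per 10 cm; age per year.
#'
#' @param data Table with covariates and `wc1`.
#' @param model A [missingness_model()] with a finite `gamma0`.
#' @return Probabilities strictly inside (0, 1).
#' @export
cdmar_probability <- function(data, model) {
  stopifnot(inherits(model, "missingness_model"))
  if (!is.finite(model$gamma0))
    stop("model intercept is not calibrated; see calibrate_intercept()")
  plogis(model$gamma0 + cdmar_eta(data, model))
}

#' Calibrate the missingness-model intercept to a target proportion
#'
#' Finds `gamma0` such that the mean predicted missingness probability over
#' the table equals `prop`, by bisection on `[-50, 50]` (the expected
#' proportion is strictly increasing in the intercept, so the root is
#' unique). Deterministic given the table.
#'
#' @param data Table with covariates and `wc1`.
#' @param model A [missingness_model()]; its intercept is ignored.
#' @param prop Target expected missingness proportion, in (0, 1).
#' @param tol Tolerance on the expected proportion.
#' @return The calibrated intercept `gamma0`.
#' @export
calibrate_intercept <- function(data, model, prop, tol = 1e-6) {
  stopifnot(inherits(model, "missingness_model"))
  if (nrow(data) == 0L) stop("table is empty")
  if (prop <= 0 || prop >= 1) stop("prop must lie strictly in (0, 1)")
  eta <- cdmar_eta(data, model)
  f <- function(g0) mean(plogis(g0 + eta)) - prop
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("cannot bracket the intercept in [-50, 50]; ",
         "missingness coefficients look pathological")
  while (TRUE) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol || (hi - lo) < 1e-12) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
}

#' Impose MCAR missingness on the wave-2 exposure
#'
#' Sets `wc2` to `NA` for an exact-count simple random subset of
#' `round(prop * n)` subjects, independently of all data columns.
#'
#' @param data Table with a `wc2` column.
#' @param prop Proportion to ampute, in `[0, 1)`.
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return `data` with amputed `wc2`; no other column is touched.
#' @export
impose_mcar <- function(data, prop, seed = NULL) {
  if (prop < 0 || prop >= 1) stop("prop must lie in [0, 1)")
  n <- nrow(data)
  k <- round(prop * n)
  with_seed(seed, {
    if (k > 0) data$wc2[sample.int(n, k)] <- NA_real_
    data
  })
}

#' Impose covariate-dependent MAR missingness on the wave-2 exposure
#'
#' Calibrates the model intercept to the target proportion (unless the
#' model already carries a finite `gamma0`), then draws independent
#' Bernoulli missingness indicators at each subject's predicted
#' probability. The realised proportion is stochastic with expectation
#' `prop`; missingness depends on `wc1` and the covariates but,
#' conditionally on them, not on `wc2`.
#'
#' @param data Table with covariates, `wc1` and `wc2`.
#' @param model A [missingness_model()].
#' @param prop Target expected missingness proportion, in (0, 1).
#' @param seed Optional integer seed (caller's RNG state restored).
#' @param tol Calibration tolerance (see [calibrate_intercept()]).
#' @return `data` with amputed `wc2`; attribute `"gamma0"` records the
#'   calibrated intercept.
#' @export
impose_cdmar <- function(data, model, prop, seed = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "missingness_model"))
  g0 <- if (is.finite(model$gamma0)) model$gamma0 else
    calibrate_intercept(data, model, prop, tol)
  p <- plogis(g0 + cdmar_eta(data, model))
  with_seed(seed, {
    miss <- runif(nrow(data)) < p
    data$wc2[miss] <- NA_real_
    attr(data, "gamma0") <- g0
    data
  })
}

# Dispatch on the mechanism named in a sim_config missingness block.
ampute <- function(data, missingness, seed = NULL) {
  switch(missingness$mechanism,
    MCAR = impose_mcar(data, missingness$prop, seed),
    CDMAR_STD = impose_cdmar(data, missingness_model("standard"),
                             missingness$prop, seed,
                             tol = missingness$tol %||% 1e-6),
    CDMAR_ENH = impose_cdmar(data, missingness_model("enhanced"),
                             missingness$prop, seed,
                             tol = missingness$tol %||% 1e-6),
    stop("unknown missingness mechanism: ", missingness$mechanism)
  )
}
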