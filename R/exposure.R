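# Paired waist-circumference measurements. Given the fixed covariates, the
# two waves are one bivariate normal draw per subject: covariate-dependent
# means plus a correlated residual pair. Default parameters are calibrated
# in closed form so the marginal scale is mean 85 cm / SD 13 cm and the
# marginal wave-1/wave-2 correlation is 0.81.

#' Exposure model parameters
#'
#' Builds the conditional bivariate-normal model for waist circumference at
#' the two waves. Both waves share the covariate slopes `coef`; wave 2 adds
#' `wave2_shift` cm to the intercept. When `residual_cov` is `NULL` it is
#' calibrated analytically: with `v = Var(coef' X)` computed exactly from
#' the cohort configuration, the residual variance is
#' `s2 = marginal_sd^2 - v` and the residual correlation
#' `r = (marginal_cor * marginal_sd^2 - v) / s2`, which makes the marginal
#' SD and the marginal correlation of the two waves equal their targets.
#'
#' @param cohort A [cohort_config()]; needed for the calibration moments.
#' @param coef Named covariate slopes in cm, shared by both waves.
#' @param marginal_mean Target marginal mean of wave-1 waist (cm).
#' @param wave2_shift Mean wave-2 minus wave-1 difference (cm).
#' @param marginal_sd Target marginal SD (cm), both waves.
#' @param marginal_cor Target marginal correlation of the two waves.
#' @param residual_cov Optional explicit 2x2 residual covariance, bypassing
#'   calibration (must be symmetric positive definite, or all-zero for the
#'   degenerate deterministic model).
#' @return A list of class `exposure_params` with `coef_w1`, `coef_w2`
#'   (each intercept + slopes) and `residual_cov`.
#' @export
exposure_params <- function(cohort = cohort_config(),
                            coef = default_exposure_coef(),
                            marginal_mean = 85, wave2_shift = 1.5,
                            marginal_sd = 13, marginal_cor = 0.81,
                            residual_cov = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  mom <- covariate_lincomb_moments(coef, cohort)
  if (is.null(residual_cov)) {
    s2 <- marginal_sd^2 - mom$var
    if (s2 <= 0)
      stop("covariate effects explain more than the target marginal ",
           "variance; increase marginal_sd or shrink coefficients")
    r <- (marginal_cor * marginal_sd^2 - mom$var) / s2
    if (abs(r) >= 1)
      stop("target marginal correlation is unattainable with these ",
           "covariate effects")
    residual_cov <- s2 * matrix(c(1, r, r, 1), 2L)
  }
  check_residual_cov(residual_cov)
  intercept <- marginal_mean - mom$mean
  structure(list(
    coef_w1 = c(intercept = intercept, coef),
    coef_w2 = c(intercept = intercept + wave2_shift, coef),
    residual_cov = residual_cov
  ), class = "exposure_params")
}

check_residual_cov <- function(V) {
  if (!is.matrix(V) || !all(dim(V) == 2L) || abs(V[1, 2] - V[2, 1]) > 1e-12)
    stop("residual_cov must be a symmetric 2x2 matrix")
  if (all(V == 0)) return(invisible(TRUE))  # degenerate deterministic model
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("residual_cov must be positive definite")
  invisible(TRUE)
}

# residual correlation implied by an exposure_params object
residual_correlation <- function(params) {
  V <- params$residual_cov
  if (all(V == 0)) return(NA_real_)
  V[1, 2] / sqrt(V[1, 1] * V[2, 2])
}

#' Simulate paired waist-circumference measurements
#'
#' Appends columns `wc1` and `wc2` (cm) to the covariate table, drawing one
#' bivariate normal residual pair per subject around the covariate-dependent
#' means. Both waves are fully observed at this stage; missingness is
#' imposed later by the amputation functions.
#'
#' @param data Covariate table from [generate_covariates()].
#' @param params An [exposure_params()] object.
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return `data` with `wc1`, `wc2` columns added.
#' @export
simulate_waist <- function(data, params = NULL, seed = NULL) {
  if (nrow(data) == 0L) stop("covariate table is empty")
  params <- params %||% exposure_params()
  stopifnot(inherits(params, "exposure_params"))
  check_residual_cov(params$residual_cov)
  X <- cbind(intercept = 1, covariate_design(data))
  expand <- function(b) {  # absent covariate names carry coefficient 0
    full <- setNames(numeric(ncol(X)), colnames(X))
    full[names(b)] <- b
    full
  }
  mu1 <- drop(X %*% expand(params$coef_w1))
  mu2 <- drop(X %*% expand(params$coef_w2))
  n <- nrow(data)
  with_seed(seed, {
    if (all(params$residual_cov == 0)) {
      e <- matrix(0, n, 2L)
    } else {
      L <- chol(params$residual_cov)
      e <- matrix(rnorm(2L * n), n, 2L) %*% L
    }
    data$wc1 <- mu1 + e[, 1L]
    data$wc2 <- mu2 + e[, 2L]
    data
  })
}
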