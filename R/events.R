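# Time-to-event generation. Cancer and death times are drawn independently
# given covariates from Weibull proportional-hazards models on the
# years-from-wave-2 clock, then administratively censored and expressed on
# the age time scale (entry at age + wave_gap) for analysis.

#' Invert a Weibull survivor function
#'
#' Under `S(t | lp) = exp(-scale * t^shape * exp(lp))`, returns the time at
#' which the survivor function equals `u`, i.e.
#' `t = (-log(u) / (scale * exp(lp)))^(1/shape)`. Supplying `u ~ U(0, 1)`
#' yields a draw from the model (inverse-transform sampling).
#'
#' @param u Uniform(0,1) draw(s), strictly inside the unit interval.
#' @param shape,scale Weibull parameters, both positive.
#' @param lp Linear predictor(s), recycled against `u`.
#' @return Event time(s) in years, strictly positive.
#' @export
#' @examples
#' weibull_time(exp(-0.01), shape = 1, scale = 0.01, lp = 0)  # 1 year
weibull_time <- function(u, shape, scale, lp = 0) {
  stopifnot(shape > 0, scale > 0)
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  (-log(u) / (scale * exp(lp)))^(1 / shape)
}

#' Simulate survival records for the cohort
#'
#' Draws time to colorectal cancer and time to death for every subject,
#' applies administrative censoring at `admin_window` years after wave 2,
#' and records follow-up on the age scale. A subject has an event when the
#' cancer time precedes both death and the administrative boundary;
#' otherwise the exit is the earlier of death and the boundary, with
#' `censor_cause` set to `"death"` or `"administrative"`.
#'
#' @param data Table with covariates and fully observed `wc1`, `wc2`
#'   (outcome generation precedes amputation by construction).
#' @param params An [event_params()] object.
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return `data` with columns `entry_age`, `exit_age`, `event` (1 =
#'   colorectal cancer), `censor_cause` (`NA` for events) appended.
#' @export
simulate_outcomes <- function(data, params = NULL, seed = NULL) {
  params <- params %||% event_params()
  stopifnot(inherits(params, "event_params"))
  if (!all(c("wc1", "wc2") %in% names(data)))
    stop("exposures must be simulated before outcomes")
  if (anyNA(data$wc1) || anyNA(data$wc2))
    stop("exposures contain missing values; amputation must come after ",
         "outcome generation")
  n <- nrow(data)
  lp_c <- linear_predictor(params$cancer$coef, data,
                           wc1 = data$wc1, wc2 = data$wc2)
  lp_d <- linear_predictor(params$death$coef, data,
                           wc1 = data$wc1, wc2 = data$wc2)
  A <- params$admin_window
  with_seed(seed, {
    t_cancer <- weibull_time(runif(n), params$cancer$shape,
                             params$cancer$scale, lp_c)
    t_death <- weibull_time(runif(n), params$death$shape,
                            params$death$scale, lp_d)
    event <- as.integer(t_cancer <= pmin(t_death, A))
    t_obs <- pmin(t_cancer, t_death, A)
    data$entry_age <- data$age + data$wave_gap
    data$exit_age <- data$entry_age + t_obs
    data$event <- event
    data$censor_cause <- ifelse(event == 1L, NA_character_,
                                ifelse(t_death < A, "death",
                                       "administrative"))
    data
  })
}
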