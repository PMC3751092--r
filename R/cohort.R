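# Synthetic baseline covariates. The generator invents marginal
# distributions (real cohort covariate rows are not redistributable); only
# the dependence of the downstream exposure and outcome models on these
# covariates matters for the simulation conclusions.

#' Generate a synthetic cohort covariate table
#'
#' Draws `n` subjects with age uniform on `[age_min, age_max]`, a binary
#' female indicator and five categorical lifestyle/demographic factors with
#' configured prevalences. Covariates are mutually independent unless the
#' `smoking_by_sex` hook of [cohort_config()] is set, in which case smoking
#' prevalences differ by sex.
#'
#' @param n Number of subjects; overrides `config$n` when given.
#' @param config A [cohort_config()] object (holds the prevalences).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards, so the same seed always yields the same table.
#' @return A `data.frame` with columns `subject_id`, `age`, `female`,
#'   `education`, `cob`, `smoking`, `physical`, `alcohol`, `wave_gap`.
#'   Factors carry the canonical level sets; `female` is 0/1 integer.
#' @export
#' @examples
#' cov <- generate_covariates(100, seed = 1)
#' range(cov$age)
generate_covariates <- function(n = NULL, config = cohort_config(),
                                seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(n %||% config$n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  prev <- config$prevalence
  with_seed(seed, {
    age <- runif(n, config$age_min, config$age_max)
    female <- rbinom(n, 1L, prev$female)
    draw_cat <- function(var) {
      factor(sample(COHORT_LEVELS[[var]], n, replace = TRUE,
                    prob = prev[[var]]),
             levels = COHORT_LEVELS[[var]])
    }
    if (is.null(config$smoking_by_sex)) {
      smoking <- draw_cat("smoking")
    } else {
      smoking <- character(n)
      for (sx in c(0L, 1L)) {
        idx <- female == sx
        p <- config$smoking_by_sex[[if (sx == 1L) "female" else "male"]]
        smoking[idx] <- sample(COHORT_LEVELS$smoking, sum(idx),
                               replace = TRUE, prob = p)
      }
      smoking <- factor(smoking, levels = COHORT_LEVELS$smoking)
    }
    data.frame(
      subject_id = seq_len(n),
      age = age,
      female = female,
      education = draw_cat("education"),
      cob = draw_cat("cob"),
      smoking = smoking,
      physical = draw_cat("physical"),
      alcohol = draw_cat("alcohol"),
      wave_gap = config$wave_gap
    )
  })
}

# Canonical k-1 indicator expansion of the covariate table. Column order is
# fixed so coefficient vectors in configs can be matched by name.
covariate_design <- function(data) {
  cbind(
    age = data$age,
    female = as.numeric(data$female),
    education_secondary = as.numeric(data$education == "secondary"),
    education_tertiary = as.numeric(data$education == "tertiary"),
    cob_uk = as.numeric(data$cob == "uk"),
    cob_mediterranean = as.numeric(data$cob == "mediterranean"),
    smoking_former = as.numeric(data$smoking == "former"),
    smoking_current = as.numeric(data$smoking == "current"),
    physical_low = as.numeric(data$physical == "low"),
    physical_moderate = as.numeric(data$physical == "moderate"),
    physical_high = as.numeric(data$physical == "high"),
    alcohol_low = as.numeric(data$alcohol == "low"),
    alcohol_moderate = as.numeric(data$alcohol == "moderate"),
    alcohol_high = as.numeric(data$alcohol == "high")
  )
}

# Evaluate a named coefficient vector against the design; names absent from
# the design (other than the handled specials) are an error.
linear_predictor <- function(coef, data, wc1 = NULL, wc2 = NULL) {
  X <- covariate_design(data)
  lp <- numeric(nrow(data))
  for (nm in names(coef)) {
    lp <- lp + coef[[nm]] * switch(nm,
      wc_change = wc2 - wc1,
      wc1 = wc1,
      wc2 = wc2,
      {
        if (!nm %in% colnames(X)) stop("unknown coefficient name: ", nm)
        X[, nm]
      })
  }
  lp
}

# Exact mean and variance of a linear combination b'X of the covariates
# under a cohort_config, by enumeration of the categorical joint
# distribution (respecting the smoking-by-sex hook) plus the uniform age
# term. Used to calibrate the exposure residual covariance in closed form.
covariate_lincomb_moments <- function(coef, config) {
  pick <- function(nm) if (nm %in% names(coef)) coef[[nm]] else 0
  prev <- config$prevalence
  mom <- function(values, probs) {
    m <- sum(values * probs)
    list(mean = m, var = sum(values^2 * probs) - m^2)
  }
  cat_vals <- function(var) {
    vapply(COHORT_LEVELS[[var]], function(lv) {
      nm <- paste(var, lv, sep = "_")
      if (nm %in% names(coef)) coef[[nm]] else 0
    }, numeric(1))
  }
  total_mean <- 0
  total_var <- 0
  # age ~ uniform(age_min, age_max)
  b_age <- pick("age")
  total_mean <- total_mean + b_age * (config$age_min + config$age_max) / 2
  total_var <- total_var + b_age^2 * (config$age_max - config$age_min)^2 / 12
  indep <- c("education", "cob", "physical", "alcohol")
  if (is.null(config$smoking_by_sex)) {
    indep <- c(indep, "smoking")
    m <- mom(c(0, pick("female")), c(1 - prev$female, prev$female))
    total_mean <- total_mean + m$mean
    total_var <- total_var + m$var
  } else {
    # joint enumeration of (sex, smoking)
    vals <- c()
    probs <- c()
    sm <- cat_vals("smoking")
    for (sx in c(0, 1)) {
      p_sx <- if (sx == 1) prev$female else 1 - prev$female
      psm <- config$smoking_by_sex[[if (sx == 1) "female" else "male"]]
      vals <- c(vals, sx * pick("female") + sm)
      probs <- c(probs, p_sx * psm)
    }
    m <- mom(vals, probs)
    total_mean <- total_mean + m$mean
    total_var <- total_var + m$var
  }
  for (var in indep) {
    m <- mom(cat_vals(var), prev[[var]])
    total_mean <- total_mean + m$mean
    total_var <- total_var + m$var
  }
  list(mean = total_mean, var = total_var)
}
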