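# Experiment driver. A scenario cell repeats the pipeline over replicates
# run under disjoint RNG streams spawned from the master seed, analyses
# each amputed dataset by complete-case deletion and by multiple
# imputation under both analysis models, and reduces the estimates to
# bias, empirical SE and coverage with Monte Carlo errors. Truth for model
# (a) is log(true_hr) by construction; truth for model (b) is the mean
# complete-data model-(b) estimate from a separate reference run, because
# model (b) deliberately omits wave-1 waist from the adjustment set.

#' Simulate one complete dataset
#'
#' Convenience wrapper chaining [generate_covariates()],
#' [simulate_waist()] and [simulate_outcomes()] under one seed. No
#' missingness is imposed.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (caller's RNG state restored).
#' @return A complete simulated dataset.
#' @export
sim_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    d <- generate_covariates(config = cfg$cohort)
    d <- simulate_waist(d, cfg$exposure)
    simulate_outcomes(d, cfg$events)
  })
}

#' Multiple-imputation estimate for one analysis model
#'
#' Imputes the amputed table `m` times, fits the requested Cox model to
#' each completed dataset, and pools by Rubin's rules.
#'
#' @param data Amputed table.
#' @param model `"a"` or `"b"`.
#' @param m Number of imputations.
#' @param seed Optional integer seed (see [impute()]).
#' @param mi_opts List of imputation design switches as in [sim_config()]'s
#'   `mi` block.
#' @return A [rubin_pool()] `pooled_result`.
#' @export
mi_estimate <- function(data, model = c("a", "b"), m = 20, seed = NULL,
                        mi_opts = list()) {
  model <- match.arg(model)
  completed <- impute(
    data, m = m, seed = seed,
    use_event_indicator = mi_opts$use_event_indicator %||% TRUE,
    use_nelson_aalen = mi_opts$use_nelson_aalen %||% TRUE,
    use_lifestyle_aux = mi_opts$use_lifestyle_aux %||% TRUE)
  fits <- lapply(completed, fit_cox, model = model)
  rubin_pool(vapply(fits, `[[`, numeric(1), "target_loghr"),
             vapply(fits, `[[`, numeric(1), "se")^2)
}

#' Run one replicate of a scenario cell
#'
#' Generates a dataset, amputes it per the configured mechanism, and
#' analyses it by complete-case deletion and multiple imputation under
#' both analysis models. With `index` given, the replicate runs under the
#' `index`-th RNG stream spawned from the config's master seed, exactly as
#' inside [run_cell()], so any replicate reproduces in isolation.
#'
#' @param cfg A [sim_config()].
#' @param index Replicate number (stream selector), or `NULL` to draw from
#'   the current RNG state.
#' @return A data.frame with one row per (analysis, method): columns
#'   `analysis`, `method`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
run_replicate <- function(cfg, index = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  body <- function() {
    d <- sim_dataset(cfg)
    d <- ampute(d, cfg$missingness)
    rows <- list()
    for (an in c("a", "b")) {
      cc <- complete_case_estimate(d, an)
      rows[[paste0(an, "_cc")]] <- data.frame(
        analysis = an, method = "complete_case",
        estimate = cc$target_loghr, se = cc$se,
        ci_low = cc$ci95[1], ci_high = cc$ci95[2])
      if (anyNA(d$wc2)) {
        mi <- mi_estimate(d, an, m = cfg$mi$m, mi_opts = cfg$mi)
        est <- mi$qbar; se <- mi$se; ci <- mi$ci95
      } else {
        est <- cc$target_loghr; se <- cc$se; ci <- cc$ci95
      }
      rows[[paste0(an, "_mi")]] <- data.frame(
        analysis = an, method = "MI", estimate = est, se = se,
        ci_low = ci[1], ci_high = ci[2])
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (is.null(index)) return(body())
  stream <- rng_streams(cfg$run$master_seed, index)[[index]]
  with_rng_state(stream, body())
}

#' Reduce replicate estimates to performance metrics
#'
#' @param estimates Per-replicate point estimates.
#' @param ci_low,ci_high Per-replicate 95% interval limits.
#' @param truth True (or reference) value of the estimand.
#' @param ses Optional per-replicate model standard errors (reported as
#'   `mean_model_se`).
#' @return One-row data.frame: `bias` (mean estimate minus truth),
#'   `emp_se` (SD of estimates, denominator `nsim - 1`), `coverage`
#'   (percentage of intervals containing truth), `mc_se_mean`
#'   (`emp_se / sqrt(nsim)`), `mc_se_coverage` (binomial SE of coverage,
#'   percentage points), `mean_model_se`, `nsim`.
#' @export
#' @examples
#' compute_metrics(c(0.4, 0.6), c(0, 0.1), c(0.8, 1.1), truth = 0.5)
compute_metrics <- function(estimates, ci_low, ci_high, truth, ses = NULL) {
  nsim <- length(estimates)
  if (nsim < 2) stop("at least 2 replicates are required")
  if (length(ci_low) != nsim || length(ci_high) != nsim)
    stop("estimates and interval limits have mismatched lengths")
  cover <- mean(ci_low <= truth & truth <= ci_high)
  emp_se <- sd(estimates)
  data.frame(
    bias = mean(estimates) - truth,
    emp_se = emp_se,
    coverage = 100 * cover,
    mc_se_mean = emp_se / sqrt(nsim),
    mc_se_coverage = 100 * sqrt(cover * (1 - cover) / nsim),
    mean_model_se = if (is.null(ses)) NA_real_ else mean(ses),
    nsim = nsim
  )
}

#' Complete-data reference values
#'
#' Runs `nsim_ref` complete (un-amputed) replicates and returns the truth
#' conventions of the study: truth for analysis (a) is `log(true_hr)` by
#' construction; truth for analysis (b) is the mean complete-data
#' model-(b) estimate; the "complete" standard error for each analysis is
#' the mean of the complete-data model standard errors. Reference
#' replicates run under streams spawned from a seed offset from the master
#' seed so they never overlap the scenario replicates.
#'
#' @param cfg A [sim_config()].
#' @param nsim_ref Number of complete replicates (default from config).
#' @return A list with `truth_a`, `truth_b`, `complete_se_a`,
#'   `complete_se_b`, `emp_se_a`, `emp_se_b`, `nsim_ref`.
#' @export
complete_reference <- function(cfg, nsim_ref = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  nsim_ref <- nsim_ref %||% cfg$run$nsim_ref
  if (nsim_ref < 1) stop("nsim_ref must be at least 1")
  streams <- rng_streams(cfg$run$master_seed + 999983L, nsim_ref)
  out <- matrix(NA_real_, nsim_ref, 4L,
                dimnames = list(NULL, c("est_a", "se_a", "est_b", "se_b")))
  for (i in seq_len(nsim_ref)) {
    out[i, ] <- with_rng_state(streams[[i]], {
      d <- sim_dataset(cfg)
      fa <- fit_model_a(d)
      fb <- fit_model_b(d)
      c(fa$target_loghr, fa$se, fb$target_loghr, fb$se)
    })
  }
  list(truth_a = log(cfg$events$true_hr),
       truth_b = mean(out[, "est_b"]),
       complete_se_a = mean(out[, "se_a"]),
       complete_se_b = mean(out[, "se_b"]),
       emp_se_a = if (nsim_ref > 1) sd(out[, "est_a"]) else NA_real_,
       emp_se_b = if (nsim_ref > 1) sd(out[, "est_b"]) else NA_real_,
       nsim_ref = nsim_ref)
}

#' Run one scenario cell
#'
#' Executes `nsim` replicates of generate / ampute / analyse under
#' disjoint RNG streams and reduces the four (analysis, method) series to
#' performance metrics. A replicate that errors is recorded; the cell
#' aborts if more than 1% of replicates fail (silent dropping would bias
#' the metrics).
#'
#' @param cfg A [sim_config()] describing the cell.
#' @param reference Optional precomputed [complete_reference()] result
#'   (computed on the fly when `NULL`; it depends only on the generator
#'   settings, not on the missingness mechanism, so it can be shared
#'   across cells of a grid).
#' @return A list: `metrics` (4-row data.frame keyed by analysis and
#'   method, with scenario identifiers), `draws` (per-replicate
#'   estimates), `reference`, `failures`.
#' @export
run_cell <- function(cfg, reference = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  nsim <- cfg$run$nsim
  reference <- reference %||% complete_reference(cfg)
  streams <- rng_streams(cfg$run$master_seed, nsim)
  draws <- vector("list", nsim)
  failures <- character(0)
  for (i in seq_len(nsim)) {
    res <- tryCatch(
      with_rng_state(streams[[i]], run_replicate(cfg, index = NULL)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", i,
                                      conditionMessage(res)))
    } else {
      res$replicate <- i
      draws[[i]] <- res
    }
  }
  if (length(failures) > 0.01 * nsim)
    stop("more than 1% of replicates failed:\n  ",
         paste(head(failures, 5L), collapse = "\n  "))
  draws <- do.call(rbind, draws)
  metrics <- list()
  for (an in c("a", "b")) {
    truth <- if (an == "a") reference$truth_a else reference$truth_b
    for (meth in c("complete_case", "MI")) {
      sub <- draws[draws$analysis == an & draws$method == meth, ]
      row <- compute_metrics(sub$estimate, sub$ci_low, sub$ci_high, truth,
                             ses = sub$se)
      metrics[[paste(an, meth)]] <- cbind(
        data.frame(analysis = an, method = meth,
                   mechanism = cfg$missingness$mechanism,
                   prop_missing = cfg$missingness$prop,
                   true_hr = cfg$events$true_hr, truth = truth,
                   n = cfg$cohort$n, m = cfg$mi$m),
        row)
    }
  }
  list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
       draws = draws, reference = reference, failures = failures)
}

#' Run the factorial scenario grid
#'
#' Loops [run_cell()] over the configured mechanisms, missingness
#' proportions and true hazard ratios (the study grid is 3 mechanisms x 3
#' proportions x 2 hazard ratios, each cell analysed by 2 methods under 2
#' analysis models). The complete-data reference is computed once per
#' hazard ratio and shared. Deterministic given the master seed.
#'
#' @param cfg Base [sim_config()]; its `grid` element defines the factor
#'   levels, the remaining elements the shared settings.
#' @param out_dir Optional directory: writes `metrics.csv`,
#'   `reference.csv` and (when ggplot2 is available) bias / empirical-SE /
#'   coverage figures faceted by mechanism.
#' @return The full metrics data.frame (one row per cell x analysis x
#'   method), invisibly carrying the per-HR references as attribute
#'   `"reference"`.
#' @export
run_grid <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  refs <- list()
  rows <- list()
  for (hr in cfg$grid$true_hrs) {
    hr_cfg <- cfg
    hr_cfg$events <- event_params(true_hr = hr, profile = cfg$events$profile,
                                  admin_window = cfg$events$admin_window)
    refs[[as.character(hr)]] <- complete_reference(hr_cfg)
    for (mech in cfg$grid$mechanisms) {
      for (prop in cfg$grid$props) {
        cell_cfg <- hr_cfg
        cell_cfg$missingness$mechanism <- mech
        cell_cfg$missingness$prop <- prop
        cell <- run_cell(cell_cfg, reference = refs[[as.character(hr)]])
        rows[[paste(hr, mech, prop)]] <- cell$metrics
      }
    }
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(metrics, "reference") <- refs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    ref_df <- do.call(rbind, lapply(names(refs), function(hr)
      cbind(data.frame(true_hr = as.numeric(hr)),
            as.data.frame(refs[[hr]]))))
    write.csv(ref_df, file.path(out_dir, "reference.csv"),
              row.names = FALSE)
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      for (metric in c("bias", "emp_se", "coverage")) {
        p <- plot_metrics(metrics, metric)
        ggplot2::ggsave(file.path(out_dir, paste0(metric, ".png")), p,
                        width = 8, height = 5, dpi = 150)
      }
    }
  }
  invisible(metrics)
}
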