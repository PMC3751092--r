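test_that("metric reduction matches hand-computed cases", {
  m <- compute_metrics(c(0.4, 0.6), c(0, 0.1), c(0.8, 1.1), truth = 0.5)
  expect_equal(m$bias, 0)
  expect_equal(m$emp_se, sqrt(0.02))
  expect_equal(m$coverage, 100)
  expect_equal(m$mc_se_mean, sqrt(0.02) / sqrt(2))
  # intervals covering everything give coverage 100 with zero MC error
  inf <- compute_metrics(c(1, 2, 3), rep(-Inf, 3), rep(Inf, 3), truth = 0)
  expect_equal(inf$coverage, 100)
  expect_equal(inf$mc_se_coverage, 0)
  expect_error(compute_metrics(1, 0, 2, 0.5), "at least 2")
  expect_error(compute_metrics(c(1, 2), 0, c(2, 3), 0.5), "mismatch")
})

test_that("nominal intervals achieve nominal coverage under normal theory", {
  set.seed(71)
  nsim <- 10000
  sigma <- 0.2
  est <- rnorm(nsim, 0.4, sigma)
  m <- compute_metrics(est, est - 1.96 * sigma, est + 1.96 * sigma,
                       truth = 0.4)
  expect_lt(abs(m$coverage - 95), 3 * m$mc_se_coverage)
})

test_that("a cell with no missing data has identical CC and MI estimates", {
  cfg <- tiny_config(prop = 0, mechanism = "MCAR")
  cell <- run_cell(cfg)
  d <- cell$draws
  for (an in c("a", "b")) {
    cc <- d[d$analysis == an & d$method == "complete_case", "estimate"]
    mi <- d[d$analysis == an & d$method == "MI", "estimate"]
    expect_identical(cc, mi)
  }
})

test_that("replicates rerun in isolation reproduce the cell draws", {
  cfg <- tiny_config(n = 600, nsim = 3, prop = 0.3, mechanism = "CDMAR_ENH")
  cell <- run_cell(cfg)
  for (i in c(1L, 3L)) {
    solo <- run_replicate(cfg, index = i)
    incell <- cell$draws[cell$draws$replicate == i, names(solo)]
    expect_equal(solo, incell, ignore_attr = TRUE)
  }
  # and the whole cell is reproducible from the master seed
  cell2 <- run_cell(cfg, reference = cell$reference)
  expect_equal(cell$metrics, cell2$metrics)
})

test_that("the complete-data reference follows the dual truth convention", {
  cfg <- tiny_config(n = 2000, nsim_ref = 4)
  ref <- complete_reference(cfg)
  expect_equal(ref$truth_a, log(1.5))
  expect_true(is.finite(ref$truth_b))
  expect_gt(ref$complete_se_a, 0)
  # a single reference replicate equals one complete-data fit
  ref1 <- complete_reference(cfg, nsim_ref = 1)
  expect_true(is.na(ref1$emp_se_b))
  # a stronger association yields a larger wave-2 reference value
  cfg_weak <- tiny_config(n = 2000, nsim_ref = 4)
  cfg_weak$events <- event_params(true_hr = 1.1, profile = "desk")
  ref_weak <- complete_reference(cfg_weak)
  expect_gt(ref$truth_b, ref_weak$truth_b)
})

test_that("the factorial grid produces one metrics row per cell and arm", {
  cfg <- tiny_config(n = 500, nsim = 3, m = 2, nsim_ref = 2)
  metrics <- run_grid(cfg, out_dir = NULL)
  # 2 HR x 3 mechanisms x 3 proportions x 2 analyses x 2 methods
  expect_equal(nrow(metrics), 72)
  expect_setequal(unique(metrics$mechanism),
                  c("MCAR", "CDMAR_STD", "CDMAR_ENH"))
  expect_setequal(unique(metrics$prop_missing), c(0.15, 0.30, 0.50))
  expect_setequal(unique(metrics$true_hr), c(1.1, 1.5))
  expect_true(all(metrics$coverage >= 0 & metrics$coverage <= 100))
  expect_true(all(metrics$emp_se > 0))
  # bit-identical on re-run with the same master seed
  metrics2 <- run_grid(cfg, out_dir = NULL)
  expect_identical(metrics, metrics2)
})

test_that("grid outputs are written as delimited text", {
  cfg <- tiny_config(n = 500, nsim = 2, m = 2, nsim_ref = 2)
  cfg$grid <- list(true_hrs = 1.5, props = 0.3, mechanisms = "MCAR")
  out <- withr::local_tempdir()
  run_grid(cfg, out_dir = out)
  metrics <- read.csv(file.path(out, "metrics.csv"))
  expect_equal(nrow(metrics), 4)
  expect_true(file.exists(file.path(out, "reference.csv")))
})

test_that("configurations round-trip through YAML", {
  cfg <- sim_config("desk", true_hr = 1.1, prop_missing = 0.15,
                    mechanism = "MCAR", n = 1234, master_seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$cohort$n, 1234)
  expect_equal(back$events$true_hr, 1.1)
  expect_equal(back$missingness, cfg$missingness)
  expect_equal(back$run, cfg$run)
  expect_equal(back$exposure, cfg$exposure)
})

test_that("datasets round-trip through CSV with empty cells for missing", {
  d <- impose_mcar(fixture_dataset(500), 0.3, seed = 72)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  raw <- readLines(path, n = 5)
  expect_false(grepl("NA", raw[2], fixed = TRUE))
  back <- read_dataset(path)
  expect_equal(back$wc2, d$wc2)
  expect_identical(levels(back$education), levels(d$education))
  expect_equal(mean(is.na(back$wc2)), mean(is.na(d$wc2)))
})
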