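# Shared fixtures, built in code at test time.

# Small scenario configuration for smoke-level pipeline tests.
tiny_config <- function(n = 800, nsim = 4, m = 2, nsim_ref = 3,
                        prop = 0.3, mechanism = "MCAR", seed = 101) {
  sim_config("desk", true_hr = 1.5, prop_missing = prop,
             mechanism = mechanism, n = n, nsim = nsim, m = m,
             nsim_ref = nsim_ref, master_seed = seed)
}

# A complete simulated dataset of moderate size, cached across tests.
.fixture_env <- new.env(parent = emptyenv())
fixture_dataset <- function(n = 4000, seed = 42) {
  key <- sprintf("data_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config("desk", n = n)
    .fixture_env[[key]] <- sim_dataset(cfg, seed = seed)
  }
  .fixture_env[[key]]
}

# A covariate table with a single repeated row (fixed covariate profile).
constant_cohort <- function(n, age = 55, female = 0L) {
  data.frame(
    subject_id = seq_len(n), age = age, female = female,
    education = factor("none_primary",
                       levels = c("none_primary", "secondary", "tertiary")),
    cob = factor("aus_nz", levels = c("aus_nz", "uk", "mediterranean")),
    smoking = factor("never", levels = c("never", "former", "current")),
    physical = factor("none", levels = c("none", "low", "moderate", "high")),
    alcohol = factor("none", levels = c("none", "low", "moderate", "high")),
    wave_gap = 13
  )
}
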