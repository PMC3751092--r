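# RNG stream management. Replicates of the experiment run under independent
# L'Ecuyer-CMRG streams spawned from one master seed, so any replicate can be
# re-run in isolation and reproduce its draws exactly. Imputations within a
# replicate use sub-streams of the replicate stream.

#' Spawn independent RNG streams from a master seed
#'
#' Creates `n` independent L'Ecuyer-CMRG generator states. Stream `i` is
#' obtained by advancing `i - 1` times from the state seeded by
#' `master_seed`, so streams are disjoint by construction.
#'
#' @param master_seed Integer seed.
#' @param n Number of streams.
#' @return A list of `n` `.Random.seed` vectors.
#' @seealso [with_rng_state()]
#' @export
rng_streams <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old_kind <- RNGkind()
  env <- globalenv()
  old_seed <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(restore_rng(old_seed, old_kind), add = TRUE)
  RNGkind("L'Ecuyer-CMRG")
  set.seed(as.integer(master_seed))
  s <- get(".Random.seed", envir = env)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[i]] <- s
  }
  out
}

#' Evaluate code under a fixed RNG state
#'
#' Installs `state` (a `.Random.seed` vector, e.g. one element of
#' [rng_streams()]) as the generator state, evaluates `code`, and restores
#' the previous state afterwards.
#'
#' @param state A `.Random.seed` vector.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_rng_state <- function(state, code) {
  env <- globalenv()
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(restore_rng(old_seed, old_kind), add = TRUE)
  assign(".Random.seed", state, envir = env)
  force(code)
}

restore_rng <- function(old_seed, old_kind) {
  env <- globalenv()
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = env)
  } else {
    suppressWarnings(RNGkind(old_kind[1L], old_kind[2L], old_kind[3L]))
    if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }
  invisible(NULL)
}

# Run `code` after set.seed(seed) when seed is given; restore the caller's
# RNG state afterwards (repeated calls with the same seed are identical and
# do not perturb the surrounding stream). seed = NULL draws from the current
# state without restoring, so pipelines advance naturally.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(restore_rng(old_seed, old_kind), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# TRUE when the active generator state is an L'Ecuyer-CMRG state (needed for
# sub-stream spawning inside impute()).
rng_is_lecuyer <- function() {
  env <- globalenv()
  exists(".Random.seed", envir = env, inherits = FALSE) &&
    get(".Random.seed", envir = env)[1L] %% 100L == 7L
}
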