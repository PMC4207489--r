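# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never perturb the
#' caller's RNG stream. All exported functions that consume randomness take an
#' explicit `seed` and route it through here.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seeds derived from one master seed. Kept below 2^31.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

# Fold assignment: k roughly equal folds over n units, seeded.
make_folds <- function(n, k, seed) {
  if (k < 2L) stopf("need at least 2 folds, got %d", k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Spearman correlation that records (rather than propagates) degeneracy:
# a constant vector has no rank ordering, so the correlation is reported as 0
# and flagged. Keeps CV metric vectors full-length for paired tests.
spearman_or_zero <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(value = 0, flagged = TRUE))
  list(value = stats::cor(x, y, method = "spearman"), flagged = FALSE)
}
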