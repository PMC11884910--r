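# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so that library internals never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic fold assignment for cross-validation. When `strata` is given
# (a 0/1 vector), folds are assigned within each stratum so both outcome
# classes appear in every fold whenever class counts allow it.
make_foldid <- function(n, n_folds, seed, strata = NULL) {
  with_seed(seed, {
    if (is.null(strata)) {
      sample(rep_len(seq_len(n_folds), n))
    } else {
      foldid <- integer(n)
      for (lev in unique(strata)) {
        idx <- which(strata == lev)
        foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      foldid
    }
  })
}

# Per-node fold seed derived from the configured cv_seed and the node LABEL
# (not its index), so that permuting item columns leaves each node's fold
# assignment — and hence the whole estimate — unchanged. Kept below 2^31.
fold_seed <- function(cv_seed, label) {
  (as.integer(cv_seed) %% 1000000L) * 1000L +
    sum(utf8ToInt(as.character(label))) %% 997L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_noa <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
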