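# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Chebyshev polynomial basis T_0..T_p on axis rescaled to [-1, 1];
# shared by the EMSC baseline model and the synthetic stray-light baseline.
cheb_basis <- function(axis, order) {
  stopifnot(order >= 0)
  t <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  n <- length(t)
  B <- matrix(NA_real_, n, order + 1L)
  B[, 1L] <- 1
  if (order >= 1L) B[, 2L] <- t
  if (order >= 2L) for (k in 3:(order + 1L)) B[, k] <- 2 * t * B[, k - 1L] - B[, k - 2L]
  B
}

`%||%` <- function(a, b) if (is.null(a)) b else a
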