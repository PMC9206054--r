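# Internal helpers shared across modules.

# Seed the RNG when an explicit seed is supplied; NULL leaves the current
# stream untouched so callers can manage their own reproducibility.
local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Deterministic child seed so each stochastic stage of a pipeline consumes an
# independent, reproducible stream. Lehmer step; result in [1, 2^31 - 2].
child_seed <- function(seed, index) {
  stopifnot(index >= 0)
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (i in seq_len(index + 1L)) s <- (s * 48271) %% m
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
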