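# Internal helpers shared across modules.

#' Derive a child seed from a master seed and an integer key
#'
#' Deterministic linear-congruential mix kept below 2^31 so the result is a
#' valid R integer seed. Used so that per-class shuffles, per-run splits and
#' per-proportion model fits each get an independent, reproducible stream:
#' adding a class (or run) never perturbs the seeds of the others.
#'
#' @param seed master seed (integer-like scalar)
#' @param key non-negative integer key (class index, run index, ...)
#' @return an integer in [0, 2^31 - 2]
#' @keywords internal
mix_seed <- function(seed, key) {
  s <- as.numeric(seed) %% 2147483647
  k <- as.numeric(key) %% 2147483647
  as.integer((s * 48271 + k * 16807 + 12345) %% 2147483647)
}

# stopifnot() with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
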