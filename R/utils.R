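#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish bad formats from bad inputs.
stop_trigmr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "trigmr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps seeded estimators (bootstrap, PRESSO simulations) from perturbing a
# surrounding simulation stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit seed derived from a master seed and stream indices.
# Linear congruential mixing keeps every derived seed below 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}
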