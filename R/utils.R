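# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit range.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483587L
}

# Equally spaced quantiles of a log-uniform distribution on [lo, hi],
# midpoint-offset so neither endpoint is returned exactly. Used for
# stratified draws of planted effect sizes: every dataset spans the range
# with a stable aggregate, only the gene assignment is randomized.
log_uniform_grid <- function(n, lo, hi) {
  stopifnot(lo > 0, hi > lo, n >= 1)
  p <- (seq_len(n) - 0.5) / n
  exp(log(lo) + p * (log(hi) - log(lo)))
}

# Round half to even (banker's rounding), as base round() does, but applied
# to cumulative sums so that differences conserve the rounded total exactly.
round_cumulative <- function(x) {
  cs <- round(cumsum(x))
  diff(c(0, cs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
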