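# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Exact area under a right-continuous step function that takes value `values[i]`
# on [breaks[i], breaks[i + 1]), integrated over [lower, upper].
step_auc <- function(breaks, values, lower, upper) {
  stopifnot(length(breaks) == length(values) + 1L, upper >= lower)
  if (upper == lower) return(0)
  lo <- pmax(breaks[-length(breaks)], lower)
  hi <- pmin(breaks[-1L], upper)
  sum(pmax(hi - lo, 0) * values)
}
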