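# Internal helpers: seeded evaluation and deterministic seed streams.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fold a vector of integers into one 32-bit seed. Linear congruential mixing;
# the multiplier is small enough that s * 69069 + x stays exact in doubles.
mix_seed <- function(...) {
  v <- as.double(unlist(list(...)))
  stopifnot(all(is.finite(v)))
  s <- 0
  for (x in v) s <- (s * 69069 + abs(x) + 1) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x)) {
    stop(sprintf("`%s` must be a single integer value", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
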