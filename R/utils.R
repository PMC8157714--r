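# internal helpers

# Evaluate code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage substream seed from a global seed (kept below 2^31).
substream_seed <- function(seed, stage) {
  stages <- c(synth = 101L, fickian = 211L, se = 307L, hop = 401L, fv = 503L,
              generic = 601L)
  off <- stages[[match.arg(stage, names(stages))]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

polyval <- function(coefficients, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) y <- y * x + coefficients[k]
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
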