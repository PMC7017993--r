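# Internal RNG helpers.
#
# Every stochastic routine in the package accepts an optional `seed`; when it
# is supplied the routine runs under that seed and restores the caller's RNG
# state afterwards, so seeded calls are pure functions of their arguments.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based substream derivation: mixes a master seed with integer indices
# (subject, box size, restart, ...) through a Lehmer step so that substreams
# are reproducible and independent of evaluation order. Result is in
# [1, 2^31 - 2], safe as an R integer seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483646) + 1
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
    if (s == 0) s <- 1
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fdconn <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "fdconn_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}
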