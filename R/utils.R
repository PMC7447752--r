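# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed for an independently seeded stage.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stage))) %% 1000L
  as.integer((as.double(seed) * 7919 + h * 104729 + index * 31L) %% 2147483647)
}

stop_memfir <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) stop_memfir("non-finite ", what, " are not allowed")
  invisible(x)
}

# Full-precision numeric formatting for text round-trips.
format_full <- function(x) sprintf("%.17g", x)
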