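
# Run code with a private RNG stream so library functions are deterministic
# given their seed argument and never disturb the caller's RNG state.
with_seed <- function(seed, code) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647L)
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(name, " must be a single positive integer", call. = FALSE)
  }
}
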