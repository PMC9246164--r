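#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Deterministic 31-bit hash of a character scalar (polynomial rolling hash).
# Used to derive independent replicate streams per coalition; collisions only
# correlate the noise of two coalitions and never bias expected values.
hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  m <- 2147483647
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% m
  as.integer(h)
}

# Derive a child seed from a base seed and one or more labels.
derive_seed <- function(seed, ...) {
  lab <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  as.integer((as.numeric(seed) * 48271 + hash31(lab)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
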