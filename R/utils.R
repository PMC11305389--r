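#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's
#' \code{.Random.seed} afterwards, so seeded helpers do not perturb the
#' global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Stable integer hash of a key sequence onto [1, 2^31 - 2]; used to derive
# independent RNG sub-streams so that adding cases/neurons does not shift
# draws for earlier ones.  Multiplier 69069 keeps products < 2^53 so the
# double-precision modulus is exact.
substream_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(h + 1)
}

# Lower median: for an even-length vector the smaller of the two central
# order statistics (for odd lengths, the usual median).
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
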