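`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(seed)
  code
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically mixes a master seed with up to two stream labels
#' (e.g. a subset bitmask and a randomization index) so that every unit of
#' work in a search owns an independent, order-free RNG stream: serial and
#' chunked execution see identical draws. Arithmetic is done in doubles
#' below 2^53, modulo the Mersenne prime 2^31 - 1, so the result is always
#' a valid 32-bit R seed.
#'
#' @param master master seed (any finite number).
#' @param a,b stream labels (non-negative numbers, default 0).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, a = 0, b = 0) {
  m <- 2147483647
  s <- (abs(master) %% m)
  s <- (s * 48271 + (a %% m) * 69621 + (b %% m) * 16807 + 12345) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s %% (m - 1) + 1)
}

# FNV-1a hash of a string, returned as 8 hex digits; used to stamp artifacts
# with a config fingerprint without external digest dependencies. All
# arithmetic stays exact in doubles (split multiplication below 2^53).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

clamp <- function(x, low, high) pmin(pmax(x, low), high)

# Consistent "is whole number" check for counts
is_count <- function(x, min = 1) {
  length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}
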