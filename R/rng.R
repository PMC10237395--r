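# Deterministic seeding and a small portable PRNG.
#
# Layout reproducibility must not depend on R's RNG kind or on global RNG
# state, so all pseudo-randomness in this package flows through an FNV-1a
# hash of the term IRI mixed with a user-supplied master seed, feeding a
# Park-Miller multiplicative congruential generator.  Everything is computed
# in double arithmetic kept below 2^53, so results are bit-identical across
# platforms.

# (a * b) mod 2^32 without overflowing double precision.
mulmod32 <- function(a, b) {
  a <- a %% 4294967296
  b <- b %% 4294967296
  a_hi <- a %/% 65536
  a_lo <- a %% 65536
  # a*b = a_hi*2^16*b + a_lo*b ; reduce the high part mod 2^32 first
  hi <- (a_hi * b) %% 4294967296
  ((hi * 65536) %% 4294967296 + a_lo * b) %% 4294967296
}

# FNV-1a over the UTF-8 bytes of a single string, 32-bit.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- mulmod32(h, 16777619)
  }
  h
}

#' Derive a per-IRI seed from a master seed
#'
#' Mixes a master integer seed with a byte-level hash of an IRI, giving each
#' ontology term its own stable pseudo-random stream.  Pure: equal inputs give
#' equal outputs on every platform and in every session.
#'
#' @param master_seed Integer master seed for the whole layout run.
#' @param iri Character IRI of the term.
#' @return An integer-valued double in `[1, 2^31 - 2]`, suitable as the state
#'   of a Park-Miller generator.
#' @examples
#' derive_seed(1, "http://purl.obolibrary.org/obo/OBI_0000070")
#' @export
derive_seed <- function(master_seed, iri) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed), length(iri) == 1)
  h <- fnv1a32(as.character(iri))
  # one extra avalanche round mixing in the master seed
  s <- mulmod32(h + (master_seed %% 4294967296), 2654435761)
  s <- bitwXor(as.integer(s %% 65536), as.integer(s %/% 65536)) + (s %/% 65536) * 65536
  s <- s %% 2147483647
  if (s <= 0) s <- s + 2147483646
  s
}

# Park-Miller minimal standard generator.  State must be in [1, 2^31 - 2].
lcg_next <- function(state) (16807 * state) %% 2147483647

# n uniforms in (0, 1) from a seed; returns list(u, state).
lcg_runif <- function(state, n) {
  u <- numeric(n)
  for (i in seq_len(n)) {
    state <- lcg_next(state)
    u[i] <- state / 2147483647
  }
  list(u = u, state = state)
}
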