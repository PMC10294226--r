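#' Deterministic seeded bit stream
#'
#' The codec's only source of randomness is a splitmix64 shift-multiply-xor
#' recurrence implemented in compiled code and documented in the package
#' vignette. The stream is *stateless-reproducible*: any bit (or base) of the
#' stream for a given seed can be regenerated from the pair
#' `(seed, offset)` alone, on any platform. This is what lets the decoder
#' rebuild the encoder's candidate matrices and equilibrium masks from
#' information recovered out of the DNA strands themselves.
#'
#' `prng_state()` creates a lightweight stream handle; `prng_bits()` and
#' `prng_bases()` read from it and advance its position. Both also accept a
#' bare numeric seed, in which case they read from offset `position`.
#'
#' @param seed non-negative integer-valued scalar below 2^53.
#' @param position stream offset: number of bits (for `prng_bits`) or bases
#'   (for `prng_bases`) already consumed.
#' @return `prng_state()` returns an object of class `rc_prng` with fields
#'   `seed` and `position` (in bits). `prng_bits()` returns a 0/1 integer
#'   vector, `prng_bases()` a string of A/C/G/T.
#' @examples
#' s <- prng_state(42)
#' prng_bits(s, 8)
#' prng_bases(123, 10)
#' @export
prng_state <- function(seed, position = 0) {
  .check_seed(seed)
  structure(
    list2env(list(seed = as.numeric(seed), position = as.numeric(position))),
    class = "rc_prng"
  )
}

.check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed != floor(seed) || seed >= 2^53) {
    stop("seed must be a single non-negative integer below 2^53",
         call. = FALSE)
  }
  invisible(seed)
}

#' @rdname prng_state
#' @param n number of bits or bases to draw.
#' @export
prng_bits <- function(seed, n, position = 0) {
  if (inherits(seed, "rc_prng")) {
    out <- .rc_prng_bits(seed$seed, seed$position, as.integer(n))
    seed$position <- seed$position + n
    return(out)
  }
  .check_seed(seed)
  .rc_prng_bits(seed, position, as.integer(n))
}

#' @rdname prng_state
#' @export
prng_bases <- function(seed, n, position = 0) {
  if (inherits(seed, "rc_prng")) {
    if (seed$position %% 2 != 0) {
      stop("stream position is not base-aligned", call. = FALSE)
    }
    out <- .rc_prng_bases(seed$seed, seed$position / 2, as.integer(n))
    seed$position <- seed$position + 2 * n
    return(.codes_to_seq(out))
  }
  .check_seed(seed)
  .codes_to_seq(.rc_prng_bases(seed, position, as.integer(n)))
}

#' Derive an independent substream seed
#'
#' Deterministically combines a master seed with two non-negative integer
#' labels (for example a strand index and a mask counter) into a new seed for
#' an unrelated-looking stream. Used for per-strand equilibrium masks so that
#' mask `c` of strand `i` is addressable without replaying the main stream.
#'
#' @inheritParams prng_state
#' @param a,b non-negative integer labels.
#' @return a new seed (numeric scalar below 2^53).
#' @export
derive_seed <- function(seed, a, b) {
  .check_seed(seed)
  if (a < 0 || b < 0) stop("labels must be non-negative", call. = FALSE)
  .rc_derive_seed(seed, a, b)
}

#' Derive the master seed from a 20-nt adapter sequence
#'
#' The forward adapter doubles as the PRNG seed of the whole encoding: its
#' 20 bases are packed into a 40-bit integer (A=00, T=01, C=10, G=11, first
#' base most significant) and passed through a fixed splitmix64 finalizer,
#' keeping the top 53 bits so the seed is exactly representable as an R
#' double. With `mix = FALSE` the raw 40-bit packing is returned, which is
#' injective on the 4^20 adapter space.
#'
#' @param adapter a 20-character A/C/G/T string.
#' @param mix apply the mixing finalizer (default) or return the raw packing.
#' @return numeric scalar seed.
#' @examples
#' seed_from_adapter("ACGTTCGACTGATCGGATCA")
#' seed_from_adapter(strrep("A", 20), mix = FALSE) # 0: all-zero packing
#' @export
seed_from_adapter <- function(adapter, mix = TRUE) {
  .check_dna(adapter, "adapter")
  if (nchar(adapter) != 20L) {
    stop("layout error: adapter must be exactly 20 nt", call. = FALSE)
  }
  codes <- .base_codes(adapter)
  packed <- 0
  for (c in codes) packed <- packed * 4 + c   # exact: 4^20 < 2^53
  if (!mix) return(packed)
  .rc_mix53(packed)
}
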