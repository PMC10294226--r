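#' Strand field layout
#'
#' Fixed field structure of an encoded oligonucleotide, 5' to 3':
#' forward adapter, Times counter, optional row-index field, data payload,
#' XOR-equilibrium counter, XOR re-equilibrium value, XOR check, reverse
#' adapter. With the defaults (no index field) the strand is
#' 20 + 6 + 639 + 10 + 2 + 3 + 20 = 700 nt and the generator-matrix row
#' index shares the Times field (`times = attempt * 32 + row`), which
#' supports up to `K + m = 32` strands. Larger encodings carry the row index
#' in a dedicated field of `index_nt` bases (capacity `4^index_nt` rows),
#' lengthening the strand accordingly.
#'
#' @param payload_nt data payload length in nt (2 bits per base).
#' @param adapter_nt length of each adapter/primer.
#' @param times_nt Times counter field length.
#' @param index_nt row-index field length (0 = packed into Times).
#' @param eq_nt XOR-equilibrium counter field length.
#' @param re_eq_nt XOR re-equilibrium field length.
#' @param check_nt XOR check field length.
#' @return object of class `rc_layout` with the field widths, `total` strand
#'   length and `content_nt` (Times through re-equilibrium, the checksum
#'   coverage).
#' @examples
#' strand_layout()$total  # 700
#' @export
strand_layout <- function(payload_nt = 639, adapter_nt = 20, times_nt = 6,
                          index_nt = 0, eq_nt = 10, re_eq_nt = 2,
                          check_nt = 3) {
  fields <- c(payload_nt = payload_nt, adapter_nt = adapter_nt,
              times_nt = times_nt, index_nt = index_nt, eq_nt = eq_nt,
              re_eq_nt = re_eq_nt, check_nt = check_nt)
  if (any(fields != floor(fields)) || any(fields < 0)) {
    stop("field widths must be non-negative integers", call. = FALSE)
  }
  if (payload_nt < 1 || adapter_nt < 1 || times_nt < 1 || eq_nt < 1 ||
      check_nt < 1) {
    stop("payload, adapter, times, equilibrium and check fields must be ",
         "at least 1 nt", call. = FALSE)
  }
  content <- as.integer(times_nt + index_nt + payload_nt + eq_nt + re_eq_nt)
  structure(list(adapter_nt = as.integer(adapter_nt),
                 times_nt = as.integer(times_nt),
                 index_nt = as.integer(index_nt),
                 payload_nt = as.integer(payload_nt),
                 eq_nt = as.integer(eq_nt),
                 re_eq_nt = as.integer(re_eq_nt),
                 check_nt = as.integer(check_nt),
                 content_nt = content,
                 total = as.integer(2L * as.integer(adapter_nt) + content +
                                      check_nt)),
            class = "rc_layout")
}

#' @export
print.rc_layout <- function(x, ...) {
  cat(sprintf(
    "<rc_layout> %d nt: adapter %d | times %d | index %d | payload %d | eq %d | re-eq %d | check %d | adapter %d\n",
    x$total, x$adapter_nt, x$times_nt, x$index_nt, x$payload_nt, x$eq_nt,
    x$re_eq_nt, x$check_nt, x$adapter_nt))
  invisible(x)
}

# Number of row slots multiplexed into the Times field when there is no
# dedicated index field: times = attempt_counter * 32 + row_index.
.ROW_SLOTS <- 32L

#' Default adapter (primer) pair
#'
#' Two fixed 20-nt sequences used as forward/reverse adapters when none are
#' supplied: GC content 0.50, no homopolymer run above 2, no
#' micro-satellites, so they pass the default policy and keep whole-strand
#' GC centered. The forward adapter seeds the PRNG
#' (see [seed_from_adapter()]).
#'
#' @return named character vector with elements `fwd` and `rev`.
#' @export
default_adapters <- function() {
  c(fwd = "ACGTTCGACTGATCGGATCA", rev = "TGCACGATCCGTAGTCAGTA")
}

# ---- base-4 integer fields -------------------------------------------------

#' Integer <-> base-4 nucleotide field codecs
#'
#' Counter fields (Times, equilibrium, re-equilibrium, row index) store
#' non-negative integers as fixed-width big-endian base-4 numerals under the
#' A=0, T=1, C=2, G=3 digit map.
#'
#' @param value non-negative integer below `4^width`.
#' @param width field width in nt.
#' @param seq nucleotide field to decode.
#' @return `int_to_bases()` a `width`-character string; `bases_to_int()` a
#'   numeric scalar.
#' @examples
#' int_to_bases(7, 3)   # "ATG"
#' bases_to_int("ATG")  # 7
#' @export
int_to_bases <- function(value, width) {
  if (value < 0 || value != floor(value)) {
    stop("value must be a non-negative integer", call. = FALSE)
  }
  if (value >= 4^width) {
    stop("capacity error: ", value, " does not fit ", width, " nt",
         call. = FALSE)
  }
  digits <- integer(width)
  v <- value
  for (i in rev(seq_len(width))) {
    digits[i] <- v %% 4
    v <- v %/% 4
  }
  .codes_to_seq(digits)
}

#' @rdname int_to_bases
#' @export
bases_to_int <- function(seq) {
  .check_dna(seq)
  codes <- .base_codes(seq)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}
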