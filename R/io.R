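# Manifest and FASTA plumbing: everything the decoder has to be told out of
# band -- adapters, K, m, layout, policy, original file length.

#' Encoding manifest
#'
#' The manifest plus the strand FASTA are jointly sufficient to decode: it
#' carries the adapter pair (the forward adapter is the PRNG seed), K and m,
#' the field layout, the constraint policy, the original bit length, and an
#' MD5 checksum of the source data. It round-trips losslessly through JSON.
#'
#' @param adapters named character vector `c(fwd = , rev = )`.
#' @param K,m chunk and redundancy counts.
#' @param layout an [strand_layout()].
#' @param policy an [constraint_policy()].
#' @param original_bit_length bits in the source file.
#' @param checksum MD5 of the source data (optional).
#' @param search_budget,subset_samples generator-selection settings, recorded
#'   for provenance.
#' @return object of class `rc_manifest`.
#' @export
rc_manifest <- function(adapters, K, m, layout, policy, original_bit_length,
                        checksum = NULL, search_budget = 64,
                        subset_samples = 200) {
  structure(list(schema_version = 1L,
                 encoder = paste0("rcstore ",
                                  as.character(utils::packageVersion("rcstore"))),
                 adapter_fwd = unname(adapters[["fwd"]]),
                 adapter_rev = unname(adapters[["rev"]]),
                 K = as.integer(K), m = as.integer(m),
                 layout = unclass(layout)[c("adapter_nt", "times_nt",
                                            "index_nt", "payload_nt",
                                            "eq_nt", "re_eq_nt", "check_nt")],
                 policy = unclass(policy),
                 original_bit_length = as.numeric(original_bit_length),
                 checksum = checksum,
                 search_budget = search_budget,
                 subset_samples = subset_samples),
            class = "rc_manifest")
}

#' Read and write manifests as JSON
#'
#' @param manifest an `rc_manifest`.
#' @param path file path.
#' @return `read_manifest()` returns the `rc_manifest`; `write_manifest()`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lay <- do.call(strand_layout, as.list(x$layout))
  pol <- do.call(constraint_policy, as.list(x$policy))
  m <- rc_manifest(c(fwd = x$adapter_fwd, rev = x$adapter_rev), x$K, x$m,
                   lay, pol, x$original_bit_length, checksum = x$checksum,
                   search_budget = x$search_budget,
                   subset_samples = x$subset_samples)
  m$schema_version <- x$schema_version
  m$encoder <- x$encoder
  m
}

#' Read and write strand FASTA files
#'
#' Strands are written as uppercase single-line FASTA with headers
#' `rc|<row_index>|<times>|<eq_counter>`. Header metadata is a convenience
#' only: decoding relies exclusively on the sequences plus the manifest, so
#' a FASTA that has been reordered or re-headered still decodes.
#'
#' @param strands character vector of sequences.
#' @param records optional list of `rc_strand_record`s for the headers.
#' @param path file path.
#' @return `read_strand_fasta()` returns an unnamed character vector of
#'   sequences; `write_strand_fasta()` returns `path` invisibly.
#' @export
write_strand_fasta <- function(strands, path, records = NULL) {
  headers <- if (is.null(records)) {
    paste0("rc|", seq_along(strands) - 1L)
  } else {
    vapply(records, function(r) {
      paste("rc", r$row_index, r$times_value, r$eq_counter, sep = "|")
    }, character(1))
  }
  set <- Biostrings::DNAStringSet(strands)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = max(nchar(strands)))
  invisible(path)
}

#' @rdname write_strand_fasta
#' @export
read_strand_fasta <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path)))
}

#' Generate a deterministic fixture file
#'
#' Synthetic input files for tests and experiments. Content models:
#' `"random"` (uniform bytes), `"zeros"` (all-zero bytes), `"repeat"`
#' (a single repeated byte, `0xA5`), and `"biased"` (bits that are 1 with
#' probability 0.8 -- the pathological high-1-rate input that code-table
#' encoders struggle with and equilibrium masking must absorb). The preset
#' `size_bits = 29390` with `model = "random"` is the in-silico stand-in for
#' the biologically stored document (2,939 characters at 10 bits each); the
#' original text itself is not redistributed, so this is a synthetic
#' equivalent of equal size. If `size_bits` is not a multiple of 8 the last
#' byte is zero-padded and the significant length is returned alongside.
#'
#' @param size_bits number of significant bits.
#' @param model content model, one of `"random"`, `"zeros"`, `"repeat"`,
#'   `"biased"`.
#' @param seed RNG seed for the random models.
#' @param path optional path; when given the bytes are written there.
#' @return list with `data` (raw vector), `bit_length`, `model`, `seed`.
#' @export
make_fixture <- function(size_bits = 29390, model = "random", seed = 1,
                         path = NULL) {
  if (size_bits < 1) stop("size_bits must be positive", call. = FALSE)
  model <- match.arg(model, c("random", "zeros", "repeat", "biased"))
  n_bytes <- ceiling(size_bits / 8)
  data <- switch(model,
    zeros = raw(n_bytes),
    "repeat" = rep(as.raw(0xA5), n_bytes),
    random = .with_seed(seed, as.raw(sample.int(256, n_bytes,
                                                replace = TRUE) - 1L)),
    biased = .with_seed(seed, {
      bits <- rbinom(n_bytes * 8, 1, 0.8)
      .bits_to_raw(bits)
    })
  )
  # zero out padding bits past size_bits so the content is well-defined
  bits <- .raw_to_bits(data)
  if (size_bits < length(bits)) {
    bits[(size_bits + 1):length(bits)] <- 0L
    data <- .bits_to_raw(bits)
  }
  if (!is.null(path)) writeBin(data, path)
  list(data = data, bit_length = size_bits, model = model, seed = seed)
}

#' Seed-space utilization
#'
#' Fraction (as a percentage) of an `4^seed_nt` seed/address space consumed
#' by `count` distinct values -- the bookkeeping used to compare how much
#' address space fountain-style encoders burn through against the Times
#' counter of the random code.
#'
#' @param count number of values used.
#' @param seed_nt width of the address field in nt.
#' @return percentage.
#' @examples
#' seed_space_utilization(72000, 16)  # < 0.00168
#' @export
seed_space_utilization <- function(count, seed_nt) {
  if (count < 0 || seed_nt < 1) stop("invalid arguments", call. = FALSE)
  count / 4^seed_nt * 100
}
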