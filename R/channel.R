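# Error-channel simulation and the LT fountain-code baseline used for the
# robustness comparisons.

#' Error-channel configuration
#'
#' Per-base substitution/insertion/deletion probabilities, a per-strand loss
#' probability, and an RNG seed. Edits are applied independently per base;
#' insertions draw a uniform base and are placed after the edited position.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0, 1]`.
#' @param loss_rate per-strand probability in `[0, 1]`.
#' @param rng_seed integer seed making the channel reproducible.
#' @return object of class `rc_channel`.
#' @export
channel_config <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                           loss_rate = 0, rng_seed = 1) {
  rates <- c(sub_rate, ins_rate, del_rate, loss_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, loss_rate = loss_rate,
                 rng_seed = rng_seed),
            class = "rc_channel")
}

#' Corrupt strands through the error channel
#'
#' Seeded and reproducible: whole-strand loss is applied first, then
#' independent per-base edits (deletion, then substitution, then a possible
#' insertion after the base). Returns the surviving, possibly
#' length-altered strands.
#'
#' @param strands character vector of sequences.
#' @param config an [channel_config()].
#' @return character vector of corrupted strands (possibly shorter than the
#'   input when strands are lost).
#' @export
apply_channel <- function(strands, config) {
  stopifnot(inherits(config, "rc_channel"))
  .with_seed(config$rng_seed, {
    kept <- strands[runif(length(strands)) >= config$loss_rate]
    if (config$sub_rate == 0 && config$ins_rate == 0 &&
        config$del_rate == 0) {
      return(kept)
    }
    vapply(kept, function(s) {
      codes <- .base_codes(s)
      n <- length(codes)
      del <- runif(n) < config$del_rate
      sub <- runif(n) < config$sub_rate
      ins <- runif(n) < config$ins_rate
      if (any(sub)) {
        # substitute with one of the three *other* bases
        codes[sub] <- (codes[sub] + sample.int(3, sum(sub),
                                               replace = TRUE)) %% 4L
      }
      pieces <- as.list(codes)
      if (any(ins)) {
        extra <- sample.int(4, sum(ins), replace = TRUE) - 1L
        j <- 0L
        for (i in which(ins)) {
          j <- j + 1L
          pieces[[i]] <- c(pieces[[i]], extra[j])
        }
      }
      if (any(del)) {
        for (i in which(del)) pieces[[i]] <- pieces[[i]][-1L]
      }
      .codes_to_seq(unlist(pieces))
    }, character(1), USE.NAMES = FALSE)
  })
}

# ---- soliton distributions and the LT baseline ------------------------------

#' Ideal and robust soliton degree distributions
#'
#' The classical LT-code degree distributions. The ideal soliton puts mass
#' `1/K` on degree 1 and `1/(d(d-1))` on degrees `2..K`; the robust soliton
#' adds the usual tau spike at `d = K/S` (with `S = c * log(K/delta) *
#' sqrt(K)`) and tail, then renormalizes.
#'
#' @param K number of chunks (`K >= 2`).
#' @param c,delta robust-soliton parameters: `c > 0`, `delta` in (0, 1).
#'   Defaults are the common literature choices.
#' @return numeric vector of length `K`; element `d` is the probability of
#'   degree `d` (sums to 1).
#' @examples
#' ideal_soliton(4)  # 1/4, 1/2, 1/6, 1/12
#' @export
ideal_soliton <- function(K) {
  if (K < 2) stop("domain error: K must be >= 2", call. = FALSE)
  d <- 2:K
  c(1 / K, 1 / (d * (d - 1)))
}

#' @rdname ideal_soliton
#' @export
robust_soliton <- function(K, c = 0.1, delta = 0.5) {
  if (K < 2) stop("domain error: K must be >= 2", call. = FALSE)
  if (c <= 0 || delta <= 0 || delta >= 1) {
    stop("domain error: need c > 0 and delta in (0, 1)", call. = FALSE)
  }
  rho <- ideal_soliton(K)
  S <- c * log(K / delta) * sqrt(K)
  pivot <- min(floor(K / S), K)  # spike capped at K for very small K
  tau <- numeric(K)
  if (pivot >= 2) {
    d <- seq_len(pivot - 1)
    tau[d] <- S / (K * d)
    tau[pivot] <- S * log(S / delta) / K
  } else if (pivot == 1) {
    tau[1] <- S * log(S / delta) / K
  }
  (rho + tau) / sum(rho + tau)
}

#' LT-code baseline: encode and decode
#'
#' Standard Luby-transform fountain code over the same chunk sets the random
#' code uses: `lt_encode()` draws each droplet's degree from the robust
#' soliton distribution, picks that many distinct chunks uniformly, and XORs
#' them; `lt_decode()` runs belief-propagation peeling (repeatedly resolving
#' degree-1 droplets) and reports whatever subset of chunks it recovers.
#'
#' @param chunks an [segment_file()] chunk set.
#' @param n_droplets number of droplets to emit; the classical rateless
#'   parameterization is `(1 + epsilon) * K`.
#' @param seed integer seed (R RNG; the LT baseline has no cross-platform
#'   stream contract).
#' @inheritParams ideal_soliton
#' @return `lt_encode()`: list of droplets, each `list(neighbors, payload)`.
#'   `lt_decode()`: list with `chunks` (K x bits matrix), `recovered`
#'   (logical K-vector) and `complete`.
#' @export
lt_encode <- function(chunks, n_droplets, seed = 1, c = 0.1, delta = 0.5) {
  stopifnot(inherits(chunks, "rc_chunkset"))
  K <- chunks$K
  probs <- if (K >= 2) robust_soliton(K, c, delta) else 1
  .with_seed(seed, {
    lapply(seq_len(n_droplets), function(i) {
      d <- sample.int(K, 1, prob = probs)
      nb <- sort(sample.int(K, d))
      payload <- if (length(nb) == 1L) chunks$chunks[nb, ] else {
        as.integer(colSums(chunks$chunks[nb, , drop = FALSE]) %% 2L)
      }
      list(neighbors = nb, payload = payload)
    })
  })
}

#' @rdname lt_encode
#' @param droplets output of `lt_encode()` (possibly with droplets lost).
#' @param K number of chunks to recover.
#' @param chunk_bits bits per chunk.
#' @export
lt_decode <- function(droplets, K, chunk_bits) {
  chunks <- matrix(0L, K, chunk_bits)
  recovered <- rep(FALSE, K)
  queue <- droplets
  repeat {
    progress <- FALSE
    remaining <- list()
    for (dr in queue) {
      nb <- dr$neighbors
      done <- nb[recovered[nb]]
      for (j in done) {
        dr$payload <- xor(dr$payload, chunks[j, ]) * 1L
      }
      nb <- nb[!recovered[nb]]
      dr$neighbors <- nb
      if (length(nb) == 0L) next
      if (length(nb) == 1L) {
        chunks[nb, ] <- dr$payload
        recovered[nb] <- TRUE
        progress <- TRUE
      } else {
        remaining[[length(remaining) + 1L]] <- dr
      }
    }
    queue <- remaining
    if (!progress || length(queue) == 0L) break
  }
  list(chunks = chunks, recovered = recovered, complete = all(recovered))
}

# ---- recovery experiments ----------------------------------------------------

#' Recovery-rate experiment
#'
#' Sweeps an error grid and measures chunk- and file-level recovery for the
#' random code (`codec = "rc"`) or the LT baseline (`codec = "lt"`), with
#' `replicates` independent seeded runs per grid point.
#'
#' For `error_kind = "loss"` the experiment runs at packet level (a lost
#' strand is simply absent; intact strands always parse) and `levels` are
#' *counts of lost strands*, drawn uniformly without replacement. For the
#' per-base kinds (`"substitution"`, `"insertion"`, `"deletion"`,
#' RC only) the full strand pipeline runs: assembled strands are corrupted
#' by [apply_channel()] at per-base rate `level`, then parsed and decoded;
#' corrupted strands are rejected by the length/checksum screens, so these
#' kinds behave like loss at the rate the screens reject.
#'
#' RC chunk recovery counts the chunks uniquely determined by the surviving
#' rows ([gf2_solve_partial()]); LT chunk recovery counts peeled chunks.
#' File success additionally requires every recovered bit to match.
#'
#' @param codec `"rc"` or `"lt"`.
#' @param error_kind `"loss"`, `"substitution"`, `"insertion"`,
#'   `"deletion"`.
#' @param levels numeric vector: lost-strand counts (loss) or per-base rates.
#' @param replicates runs per level.
#' @param K chunks; `redundancy` extra strands/droplets are added, i.e.
#'   `m = redundancy` for RC and `n_droplets = K + redundancy` for LT.
#' @param redundancy extra strands beyond K (25% redundancy is
#'   `redundancy = K/4`).
#' @param chunk_bits bits per chunk for the packet-level experiments.
#' @param seed master seed; replicate r at level l gets an independent
#'   derived seed.
#' @param layout,policy,adapters strand-pipeline settings (per-base kinds).
#' @return data frame with columns `codec`, `error_kind`, `level`,
#'   `replicate`, `chunk_recovery`, `file_success`.
#' @export
recovery_experiment <- function(codec = c("rc", "lt"),
                                error_kind = c("loss", "substitution",
                                               "insertion", "deletion"),
                                levels = 0:4, replicates = 20,
                                K = 8, redundancy = 2, chunk_bits = 64,
                                seed = 1,
                                layout = NULL,
                                policy = constraint_policy(),
                                adapters = default_adapters()) {
  codec <- match.arg(codec)
  error_kind <- match.arg(error_kind)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (codec == "lt" && error_kind != "loss") {
    stop("the LT baseline has no strand-level representation; ",
         "only error_kind = \"loss\" is supported", call. = FALSE)
  }

  n_out <- K + redundancy
  rows <- vector("list", length(levels) * replicates)
  i <- 0L
  for (level in levels) {
    for (rep_i in seq_len(replicates)) {
      i <- i + 1L
      rep_seed <- derive_seed(seed, match(level, levels), rep_i)
      res <- if (error_kind == "loss") {
        .run_loss_replicate(codec, level, rep_seed, K, redundancy,
                            chunk_bits)
      } else {
        .run_strand_replicate(error_kind, level, rep_seed, K, redundancy,
                              chunk_bits, layout, policy, adapters)
      }
      rows[[i]] <- data.frame(codec = codec, error_kind = error_kind,
                              level = level, replicate = rep_i,
                              chunk_recovery = res$chunk_recovery,
                              file_success = res$file_success)
    }
  }
  do.call(rbind, rows)
}

# Packet-level loss replicate: encode a random chunk set, drop `level`
# packets uniformly, decode, compare.
.run_loss_replicate <- function(codec, level, rep_seed, K, redundancy,
                                chunk_bits) {
  n_out <- K + redundancy
  n_lose <- min(level, n_out)
  data_bits <- prng_bits(rep_seed, K * chunk_bits)
  chunks <- structure(list(chunks = matrix(data_bits, K, chunk_bits,
                                           byrow = TRUE),
                           K = K, chunk_bits = chunk_bits,
                           original_bit_length = K * chunk_bits),
                      class = "rc_chunkset")
  if (codec == "rc") {
    gen <- select_generator_matrix(derive_seed(rep_seed, 1, 1), K,
                                   redundancy)
    droplets <- make_droplets(chunks, gen)
    keep <- .with_seed(derive_seed(rep_seed, 2, 2),
                       sort(sample.int(n_out, n_out - n_lose)))
    part <- gf2_solve_partial(gen$matrix[keep, , drop = FALSE],
                              droplets$payload[keep, , drop = FALSE])
    ok <- part$recovered & rowSums(part$chunks != chunks$chunks) == 0L
    list(chunk_recovery = mean(ok), file_success = all(ok))
  } else {
    droplets <- lt_encode(chunks, n_out,
                          seed = derive_seed(rep_seed, 1, 1) %% 2^31)
    keep <- .with_seed(derive_seed(rep_seed, 2, 2),
                       sort(sample.int(n_out, n_out - n_lose)))
    dec <- lt_decode(droplets[keep], K, chunk_bits)
    ok <- dec$recovered & rowSums(dec$chunks != chunks$chunks) == 0L
    list(chunk_recovery = mean(ok), file_success = all(ok))
  }
}

# Full strand-pipeline replicate for per-base error kinds (RC only).
.run_strand_replicate <- function(error_kind, level, rep_seed, K,
                                  redundancy, chunk_bits, layout, policy,
                                  adapters) {
  if (is.null(layout)) layout <- strand_layout(payload_nt = chunk_bits / 2)
  stopifnot(chunk_bits == 2 * layout$payload_nt)
  data <- .bits_to_raw(prng_bits(rep_seed, K * chunk_bits))
  enc <- rc_encode(data, m = redundancy, adapters = adapters,
                   layout = layout, policy = policy,
                   bit_length = K * chunk_bits)
  cfg <- channel_config(
    sub_rate = if (error_kind == "substitution") level else 0,
    ins_rate = if (error_kind == "insertion") level else 0,
    del_rate = if (error_kind == "deletion") level else 0,
    rng_seed = derive_seed(rep_seed, 3, 3) %% 2^31)
  corrupted <- apply_channel(enc$strands, cfg)
  seed <- seed_from_adapter(enc$manifest$adapter_fwd)
  enc_layout <- do.call(strand_layout, as.list(enc$manifest$layout))
  parsed <- lapply(corrupted, parse_strand, seed = seed,
                   adapters = adapters, layout = enc_layout)
  recs <- Filter(function(p) p$ok, parsed)
  recs <- lapply(recs, `[[`, "record")
  rows <- vapply(recs, `[[`, numeric(1), "row_index")
  keep <- !duplicated(rows) & rows < K + redundancy
  recs <- recs[keep]; rows <- rows[keep]
  truth <- segment_file(data, layout$payload_nt,
                        bit_length = K * chunk_bits)
  if (length(recs) == 0L) {
    return(list(chunk_recovery = 0, file_success = FALSE))
  }
  full <- random_bit_matrix(seed, K + redundancy, K,
                            attempt = enc$generator$attempt_counter)
  payload <- do.call(rbind, lapply(recs, `[[`, "payload_bits"))
  part <- gf2_solve_partial(full[rows + 1L, , drop = FALSE], payload)
  ok <- part$recovered & rowSums(part$chunks != truth$chunks) == 0L
  list(chunk_recovery = mean(ok), file_success = all(ok))
}
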