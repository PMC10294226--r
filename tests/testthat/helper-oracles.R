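# Independent brute-force oracles. These deliberately share no code with the
# implementation paths they check.

# GF(2) rank by enumerating the full row span: the span of r rows has
# 2^rank distinct vectors. Rows are given as a 0/1 matrix.
oracle_gf2_rank <- function(m) {
  n <- nrow(m)
  span <- matrix(0L, nrow = 1, ncol = ncol(m))
  for (i in seq_len(n)) {
    shifted <- sweep(span, 2, m[i, ], function(a, b) (a + b) %% 2L)
    both <- rbind(span, shifted)
    span <- both[!duplicated(both), , drop = FALSE]
  }
  log2(nrow(span))
}

# 4x4-and-smaller rank oracle on rows packed as integers (fast enough to
# sweep all 2^16 matrices): span size via repeated XOR closure.
oracle_rank_packed <- function(rows) {
  span <- 0L
  for (r in rows) span <- unique(c(span, bitwXor(span, r)))
  log2(length(span))
}

# Longest run by a scalar scan.
oracle_max_run <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  best <- 1L
  run <- 1L
  for (i in seq_along(ch)[-1]) {
    run <- if (ch[i] == ch[i - 1]) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

# Micro-satellite oracle: enumerate every (start, unit-length) pair and apply
# the documented contract directly (primitive unit, whole-copy count,
# span/copy thresholds, leftmost anchoring).
oracle_microsats <- function(seq, policy) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  prim <- function(u) {
    lu <- length(u)
    for (d in seq_len(lu - 1)) {
      if (lu %% d == 0 && all(u == rep(u[1:d], length.out = lu))) return(FALSE)
    }
    TRUE
  }
  hits <- list()
  for (s in seq_len(n)) {
    for (u in policy$microsat_unit_min:policy$microsat_unit_max) {
      if (s + 2 * u - 1 > n) next
      unit <- ch[s:(s + u - 1)]
      if (!prim(unit)) next
      # leftmost anchoring: periodicity must not extend one base left
      if (s > 1 && ch[s - 1] == ch[s + u - 1]) next
      copies <- 1L
      while (s + (copies + 1) * u - 1 <= n &&
             all(ch[(s + copies * u):(s + (copies + 1) * u - 1)] == unit)) {
        copies <- copies + 1L
      }
      if (copies >= policy$microsat_min_copies &&
          copies * u >= policy$microsat_min_span) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s, unit = paste(unit, collapse = ""),
          copies = copies, span = copies * u)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), unit = character(),
                      copies = integer(), span = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$unit)), , drop = FALSE]
}

# Exhaustive GF(2) solver: try all 2^K chunk assignments.
oracle_solve <- function(m, payload) {
  K <- ncol(m)
  sols <- list()
  for (v in 0:(2^K - 1)) {
    x <- as.integer(intToBits(v))[1:K]
    rhs <- (m %*% matrix(x, ncol = 1)) %% 2L
    # single-bit payloads: payload is an R x 1 matrix here
    if (all(rhs == payload)) sols[[length(sols) + 1]] <- x
  }
  sols
}

# Exact P(longest homopolymer run <= max_run) for a uniform random l-mer,
# by transfer-matrix dynamic programming over the current run length.
oracle_dp_run_prob <- function(l, max_run) {
  v <- c(1, rep(0, max_run - 1))
  for (i in seq_len(l - 1)) {
    nv <- numeric(max_run)
    nv[1] <- 0.75 * sum(v)
    if (max_run >= 2) nv[2:max_run] <- 0.25 * v[1:(max_run - 1)]
    v <- nv
  }
  sum(v)
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Small chunk set built directly (bypasses file segmentation).
make_chunks <- function(K, chunk_bits, seed = 1) {
  bits <- prng_bits(seed, K * chunk_bits)
  structure(list(chunks = matrix(bits, K, chunk_bits, byrow = TRUE),
                 K = K, chunk_bits = chunk_bits,
                 original_bit_length = K * chunk_bits),
            class = "rc_chunkset")
}

# Compact layout for fast strand-level tests: 60-nt payload, 121-nt strand.
test_layout <- function() strand_layout(payload_nt = 60)

# A permissive policy for tests that exercise mechanics rather than
# screening (keeps equilibrium searches instant).
loose_policy <- function() {
  constraint_policy(max_homopolymer_run = 8, gc_min = 0.2, gc_max = 0.8,
                    check_microsat = FALSE)
}
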