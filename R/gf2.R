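#' Draw a seeded random 0/1 matrix
#'
#' Fills a `t_rows` x `k_cols` matrix row-by-row with fair coin flips from the
#' deterministic package stream, so the same `(seed, t_rows, k_cols)` always
#' yields the same matrix. Candidate generator matrices are consecutive
#' blocks of this stream: candidate `j` (0-based) starts at bit offset
#' `j * t_rows * k_cols`.
#'
#' @inheritParams prng_state
#' @param t_rows,k_cols matrix dimensions; `t_rows >= k_cols >= 1`.
#' @param attempt 0-based candidate index selecting the stream block.
#' @return integer 0/1 matrix.
#' @export
random_bit_matrix <- function(seed, t_rows, k_cols, attempt = 0) {
  if (k_cols < 1 || t_rows < k_cols) {
    stop("configuration error: need t_rows >= k_cols >= 1", call. = FALSE)
  }
  n <- t_rows * k_cols
  bits <- prng_bits(seed, n, position = attempt * n)
  matrix(bits, nrow = t_rows, ncol = k_cols, byrow = TRUE)
}

.check_bit_matrix <- function(m) {
  if (!is.matrix(m) || !all(m %in% c(0L, 1L))) {
    stop("expected a 0/1 matrix", call. = FALSE)
  }
  invisible(m)
}

#' Gaussian XOR elimination over GF(2)
#'
#' Triangularizes a square 0/1 matrix by row swaps and row XORs (addition over
#' GF(2)), returning the triangular form, the main-diagonal flags, and a
#' replayable row-operation log. The system `M x = b` has a unique solution
#' over GF(2) exactly when every main-diagonal element of the triangular form
#' is 1; `is_uniquely_solvable()` is that verdict (computed in compiled,
#' bit-packed form).
#'
#' The operation log is a list of `c("swap", i, j)` and `c("xor", target,
#' source)` steps; applying the same steps to a payload matrix mirrors the
#' elimination on the right-hand side, which is how [solve_augmented()]
#' recovers chunk data from droplets.
#'
#' @param m square 0/1 matrix.
#' @return `gauss_xor_eliminate()`: a list with `tri` (triangularized matrix),
#'   `diag` (0/1 diagonal flags) and `ops` (row-operation log).
#'   `is_uniquely_solvable()`: a logical scalar.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2)
#' gauss_xor_eliminate(m)$diag
#' is_uniquely_solvable(m)
#' @export
gauss_xor_eliminate <- function(m) {
  .check_bit_matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("shape error: matrix must be square", call. = FALSE)
  a <- m
  ops <- list()
  for (col in seq_len(n)) {
    piv <- col - 1L + which(a[col:n, col] == 1L)[1]
    if (is.na(piv)) next  # 0 stays on the diagonal: dependent rows
    if (piv != col) {
      a[c(col, piv), ] <- a[c(piv, col), ]
      ops[[length(ops) + 1L]] <- c("swap", col, piv)
    }
    if (col < n) {
      below <- col + which(a[(col + 1L):n, col] == 1L)
      for (r in below) {
        a[r, ] <- xor(a[r, ], a[col, ]) * 1L
        ops[[length(ops) + 1L]] <- c("xor", r, col)
      }
    }
  }
  list(tri = a, diag = diag(a), ops = ops)
}

#' @rdname gauss_xor_eliminate
#' @export
is_uniquely_solvable <- function(m) {
  .check_bit_matrix(m)
  if (nrow(m) != ncol(m)) {
    stop("shape error: matrix must be square", call. = FALSE)
  }
  .rc_gf2_invertible(m)
}

#' Replay a row-operation log on a payload matrix
#'
#' @param ops operation log from [gauss_xor_eliminate()].
#' @param payload matrix with one row per original matrix row.
#' @return the payload matrix after the same swaps and XORs.
#' @export
replay_ops <- function(ops, payload) {
  for (op in ops) {
    i <- as.integer(op[2]); j <- as.integer(op[3])
    if (op[1] == "swap") {
      payload[c(i, j), ] <- payload[c(j, i), ]
    } else {
      payload[i, ] <- xor(payload[i, ], payload[j, ]) * 1L
    }
  }
  payload
}

#' Select a generator matrix by seeded random sampling
#'
#' Draws candidate `(K+m) x K` matrices from the seeded stream (candidate `j`
#' is stream block `j`, recorded as `attempt_counter` -- the Times value
#' stored in every strand). A candidate is rejected outright if it has an
#' all-zero row (a droplet carrying nothing) or an uncovered column (a chunk
#' absent from every droplet). Accepted candidates are scored by the fraction
#' of K-row subsets that are uniquely solvable: all `choose(K+m, K)` subsets
#' when that count is at most `exhaustive_limit`, otherwise `subset_samples`
#' uniformly drawn subsets. The best-scoring candidate within
#' `search_budget` draws wins; ties go to the earliest draw (keeping the
#' Times counter small), and the search stops early at a perfect score.
#'
#' @inheritParams prng_state
#' @param K number of data chunks (matrix columns).
#' @param m number of redundant rows; the matrix has `K + m` rows.
#' @param search_budget maximum number of candidate draws.
#' @param subset_samples random K-subsets scored per candidate when
#'   exhaustive enumeration is too large.
#' @param exhaustive_limit enumerate all subsets when `choose(K+m, K)` is at
#'   most this.
#' @param times_capacity capacity of the Times counter field; the winning
#'   `attempt_counter` must fit it.
#' @return an object of class `rc_generator`: list with `matrix`, `seed`,
#'   `attempt_counter`, `score`, `K`, `m`.
#' @export
select_generator_matrix <- function(seed, K, m,
                                    search_budget = 64,
                                    subset_samples = 200,
                                    exhaustive_limit = 1000,
                                    times_capacity = 4^6) {
  .check_seed(seed)
  if (K < 1 || m < 0) stop("need K >= 1 and m >= 0", call. = FALSE)
  if (search_budget < 1 || subset_samples < 1) {
    stop("budgets must be >= 1", call. = FALSE)
  }
  n_rows <- K + m
  exhaustive <- choose(n_rows, K) <= exhaustive_limit
  subsets <- if (exhaustive) {
    asplit(combn(n_rows, K), 2L)
  }

  best <- NULL
  for (attempt in seq_len(search_budget) - 1L) {
    cand <- random_bit_matrix(seed, n_rows, K, attempt = attempt)
    if (any(rowSums(cand) == 0L) || any(colSums(cand) == 0L)) next
    if (!exhaustive) {
      subsets <- .with_seed(derive_seed(seed, 2^20 + attempt, 7), {
        lapply(seq_len(subset_samples), function(i) sample.int(n_rows, K))
      })
    }
    ok <- vapply(subsets, function(s) .rc_gf2_subset_invertible(cand, s),
                 logical(1))
    score <- mean(ok)
    if (score == 0) next
    if (is.null(best) || score > best$score) {
      best <- list(matrix = cand, seed = seed, attempt_counter = attempt,
                   score = score, K = K, m = m)
    }
    if (best$score == 1) break
  }
  if (is.null(best)) {
    stop("search-exhausted: no candidate with a solvable K-subset within ",
         search_budget, " draws", call. = FALSE)
  }
  if (best$attempt_counter >= times_capacity) {
    stop("capacity error: attempt_counter ", best$attempt_counter,
         " exceeds the Times field capacity ", times_capacity, call. = FALSE)
  }
  structure(best, class = "rc_generator")
}

#' @export
print.rc_generator <- function(x, ...) {
  cat(sprintf(
    "<rc_generator> (K+m) x K = %d x %d, attempt %d, score %.4f\n",
    x$K + x$m, x$K, x$attempt_counter, x$score))
  invisible(x)
}

#' Solve an augmented GF(2) system
#'
#' Given `R >= K` generator rows and their payload bit-vectors (one per row),
#' performs Gauss-Jordan elimination over GF(2), mirroring every row
#' operation on the payloads, and returns the unique chunk solution when the
#' provided rows admit one. Surplus rows that reduce to zero with a zero
#' payload are consistent and tolerated; surplus rows that reduce to zero
#' with a non-zero payload are reported by (1-based) input index in
#' `inconsistent`.
#'
#' @param m 0/1 matrix with `K` columns and at least `K` rows.
#' @param payload matrix of payload bits, one row per row of `m`.
#' @return list with `chunks` (a `K` x bits matrix) and `inconsistent`
#'   (integer indices of contradictory surplus rows).
#' @export
solve_augmented <- function(m, payload) {
  .check_bit_matrix(m)
  if (!is.matrix(payload) || nrow(payload) != nrow(m)) {
    stop("payload must have one row per matrix row", call. = FALSE)
  }
  K <- ncol(m)
  res <- .gf2_reduce(m, payload)
  if (length(res$missing) > 0L) {
    stop("undecodable: no uniquely solvable K-subset; missing pivot columns ",
         paste(res$missing, collapse = ", "), call. = FALSE)
  }
  list(chunks = res$solution, inconsistent = res$inconsistent)
}

# Gauss-Jordan reduction of an R x K system with payload right-hand sides.
# Returns pivot bookkeeping, the (possibly partial) solution, which columns
# lack pivots, which chunks are uniquely determined, and inconsistent rows.
.gf2_reduce <- function(m, payload) {
  a <- m
  p <- payload
  storage.mode(a) <- "integer"
  storage.mode(p) <- "integer"
  R <- nrow(a); K <- ncol(a)
  pivot_of <- rep(NA_integer_, K)
  used <- rep(FALSE, R)
  for (col in seq_len(K)) {
    cand <- which(!used & a[, col] == 1L)
    if (length(cand) == 0L) next
    piv <- cand[1]
    used[piv] <- TRUE
    pivot_of[col] <- piv
    hit <- setdiff(which(a[, col] == 1L), piv)
    for (r in hit) {
      a[r, ] <- xor(a[r, ], a[piv, ]) * 1L
      p[r, ] <- xor(p[r, ], p[piv, ]) * 1L
    }
  }
  missing <- which(is.na(pivot_of))
  surplus <- which(!used)
  inconsistent <- surplus[rowSums(p[surplus, , drop = FALSE]) > 0L &
                          rowSums(a[surplus, , drop = FALSE]) == 0L]
  # chunk col is determined iff its pivot row involves no free column
  determined <- !is.na(pivot_of)
  if (length(missing) > 0L) {
    for (col in which(determined)) {
      if (sum(a[pivot_of[col], ]) != 1L) determined[col] <- FALSE
    }
  }
  solution <- matrix(0L, K, ncol(payload))
  solution[determined, ] <- p[pivot_of[determined], , drop = FALSE]
  list(solution = solution, missing = missing, determined = determined,
       inconsistent = inconsistent)
}

#' Partial GF(2) recovery
#'
#' Like [solve_augmented()] but never errors: returns whatever chunks are
#' uniquely determined by the provided rows. Used by the channel simulator to
#' measure partial chunk recovery when full decoding fails.
#'
#' @inheritParams solve_augmented
#' @return list with `chunks`, logical vector `recovered`, and
#'   `inconsistent` row indices.
#' @export
gf2_solve_partial <- function(m, payload) {
  .check_bit_matrix(m)
  res <- .gf2_reduce(m, payload)
  list(chunks = res$solution, recovered = res$determined,
       inconsistent = res$inconsistent)
}
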