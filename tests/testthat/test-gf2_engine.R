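# Seeded PRNG, bit matrices, GF(2) elimination, generator selection.

test_that("adapter seed derivation packs and mixes deterministically", {
  expect_identical(seed_from_adapter(strrep("A", 20), mix = FALSE), 0)
  expect_identical(seed_from_adapter(paste0(strrep("A", 19), "T"),
                                     mix = FALSE), 1)
  # first base most significant
  expect_identical(seed_from_adapter(paste0("T", strrep("A", 19)),
                                     mix = FALSE), 4^19)
  ad <- default_adapters()[["fwd"]]
  expect_identical(seed_from_adapter(ad), seed_from_adapter(ad))
  expect_true(seed_from_adapter(ad) < 2^53)
  expect_error(seed_from_adapter("ACGTN" ), "alphabet|20 nt")
  expect_error(seed_from_adapter(strrep("N", 20)), "alphabet")
  expect_error(seed_from_adapter(strrep("A", 19)), "20 nt")
})

test_that("the bit stream is stateless-reproducible", {
  full <- prng_bits(99, 512)
  for (p in c(0, 1, 63, 64, 65, 300)) {
    expect_identical(prng_bits(99, 512 - p, position = p),
                     full[(p + 1):512])
  }
  # handle objects advance and agree with offsets
  st <- prng_state(99)
  expect_identical(prng_bits(st, 100), full[1:100])
  expect_identical(prng_bits(st, 100), full[101:200])
  # base stream is the bit stream read two bits at a time
  bases <- prng_bases(99, 16)
  expect_identical(bases_to_bits(bases), full[1:32])
  expect_error(prng_bits(-1, 4), "seed")
})

test_that("derived substream seeds separate streams", {
  s1 <- derive_seed(5, 0, 1)
  expect_identical(s1, derive_seed(5, 0, 1))
  expect_false(s1 == derive_seed(5, 0, 2))
  expect_false(s1 == derive_seed(5, 1, 1))
  expect_false(s1 == derive_seed(6, 0, 1))
})

test_that("random bit matrices are deterministic fair coins", {
  expect_identical(random_bit_matrix(7, 10, 4), random_bit_matrix(7, 10, 4))
  expect_false(identical(random_bit_matrix(7, 10, 4, attempt = 1),
                         random_bit_matrix(7, 10, 4)))
  expect_error(random_bit_matrix(7, 3, 4), "configuration")

  # overall fraction of ones within a 99% binomial CI at T=400, K=100
  m <- random_bit_matrix(123, 400, 100)
  n <- length(m)
  ci <- qnorm(c(0.005, 0.995), 0.5, sqrt(0.25 / n))
  expect_gt(mean(m), ci[1])
  expect_lt(mean(m), ci[2])
})

test_that("row degrees follow Binomial(K, 1/2): mean K/2, variance K/4", {
  K <- 23
  n <- 1e5
  deg <- rowSums(matrix(prng_bits(2024, n * K), n, K, byrow = TRUE))
  se <- sqrt(K / 4) / sqrt(n)
  expect_lt(abs(mean(deg) - K / 2), 3 * se)
  expect_lt(abs(var(deg) - K / 4) / (K / 4), 0.10)
})

test_that("elimination triangularizes with a replayable op log", {
  id <- diag(1L, 4)
  r <- gauss_xor_eliminate(id)
  expect_identical(r$diag, rep(1L, 4))
  expect_length(r$ops, 0)

  dup <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 0L, 1L))
  expect_true(0 %in% gauss_xor_eliminate(dup)$diag)

  withr::with_seed(11, {
    for (i in 1:25) {
      m <- matrix(sample(0:1, 36, replace = TRUE), 6, 6)
      r <- gauss_xor_eliminate(m)
      expect_identical(replay_ops(r$ops, m), r$tri)
      expect_identical(all(r$diag == 1L), oracle_gf2_rank(m) == 6)
    }
  })
  expect_error(gauss_xor_eliminate(matrix(0L, 2, 3)), "square")
})

test_that("solvability verdict matches brute-force rank, exhaustively to 4x4", {
  # all 512 3x3 matrices, both the R elimination and the compiled verdict
  for (v in 0:511) {
    m <- matrix(as.integer(intToBits(v))[1:9], 3, 3)
    truth <- oracle_gf2_rank(m) == 3
    expect_identical(is_uniquely_solvable(m), truth)
    expect_identical(all(gauss_xor_eliminate(m)$diag == 1L), truth)
  }
  # all 65536 4x4 matrices against the packed-span oracle (compiled path)
  bits4 <- t(vapply(0:15, function(r) as.integer(intToBits(r))[1:4],
                    integer(4)))
  bad <- 0L
  for (v in 0:65535) {
    rows <- c(v %% 16L, (v %/% 16L) %% 16L, (v %/% 256L) %% 16L,
              v %/% 4096L)
    m <- bits4[rows + 1L, , drop = FALSE]
    if (is_uniquely_solvable(m) != (oracle_rank_packed(rows) == 4)) {
      bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
  # random 8x8 spot checks with the full-span oracle
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
      expect_identical(is_uniquely_solvable(m), oracle_gf2_rank(m) == 8)
    }
  })
  expect_true(is_uniquely_solvable(diag(1L, 5)))
  expect_false(is_uniquely_solvable(rbind(c(1L, 1L), c(0L, 0L))))
})

test_that("solve_augmented recovers chunks, tolerates and flags surplus rows", {
  # identity rows return payloads unchanged
  p <- matrix(prng_bits(3, 12), 3, 4)
  expect_identical(solve_augmented(diag(1L, 3), p)$chunks, p)

  # rows {c1, c1 xor c2}
  m <- rbind(c(1L, 0L), c(1L, 1L))
  c1 <- c(1L, 0L, 1L, 1L)
  c2 <- c(0L, 0L, 1L, 0L)
  sol <- solve_augmented(m, rbind(c1, xor(c1, c2) * 1L))
  expect_identical(sol$chunks, unname(rbind(c1, c2)))

  # random solvable systems vs the exhaustive-assignment oracle (K = 6,
  # checked one payload column at a time)
  withr::with_seed(21, {
    for (i in 1:10) {
      repeat {
        m <- matrix(sample(0:1, 48, replace = TRUE), 8, 6)
        if (oracle_gf2_rank(m) == 6) break
      }
      x <- matrix(sample(0:1, 6 * 3, replace = TRUE), 6, 3)
      payload <- (m %*% x) %% 2L
      got <- solve_augmented(m, payload)
      expect_identical(got$chunks, x)
      expect_length(got$inconsistent, 0)
      for (col in 1:3) {
        sols <- oracle_solve(m, payload[, col, drop = FALSE])
        expect_length(sols, 1)
        expect_identical(sols[[1]], x[, col])
      }
    }
  })

  # inconsistent surplus row is reported by index
  m2 <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  good <- rbind(c1, c2, xor(c1, c2) * 1L)
  bad <- good
  bad[3, 1] <- 1L - bad[3, 1]
  expect_identical(solve_augmented(m2, good)$inconsistent, integer(0))
  expect_identical(solve_augmented(m2, bad)$inconsistent, 3L)

  # undecodable: missing pivot columns named
  m3 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(0L, 0L, 1L))
  expect_error(solve_augmented(m3, matrix(0L, 3, 2)),
               "undecodable.*2")
})

test_that("encode-then-solve round trip holds for solvable systems", {
  withr::with_seed(31, {
    for (i in 1:10) {
      K <- sample(2:9, 1)
      repeat {
        m <- matrix(sample(0:1, (K + 2) * K, replace = TRUE), K + 2, K)
        if (oracle_gf2_rank(m) == K) break
      }
      x <- matrix(sample(0:1, K * 5, replace = TRUE), K, 5)
      expect_identical(solve_augmented(m, (m %*% x) %% 2L)$chunks, x)
    }
  })
})

test_that("generator selection is deterministic, covering, and scored", {
  g1 <- select_generator_matrix(1234, 8, 2)
  g2 <- select_generator_matrix(1234, 8, 2)
  expect_identical(g1$matrix, g2$matrix)
  expect_identical(g1$attempt_counter, g2$attempt_counter)
  expect_identical(g1$score, g2$score)

  # m = 0: the returned matrix is square and uniquely solvable, score 1
  g0 <- select_generator_matrix(55, 6, 0)
  expect_identical(dim(g0$matrix), c(6L, 6L))
  expect_true(is_uniquely_solvable(g0$matrix))
  expect_identical(g0$score, 1)

  # K=4, m=2: reported score equals the exact fraction over all C(6,4)
  # subsets (selection enumerates exhaustively at this size)
  g <- select_generator_matrix(77, 4, 2)
  subsets <- combn(6, 4)
  manual <- mean(apply(subsets, 2, function(s) {
    is_uniquely_solvable(g$matrix[s, , drop = FALSE])
  }))
  expect_equal(g$score, manual)

  # every returned matrix covers all columns and has no zero row
  for (seed in c(3, 14, 159, 2653)) {
    gg <- select_generator_matrix(seed, 7, 2)
    expect_true(all(colSums(gg$matrix) >= 1))
    expect_true(all(rowSums(gg$matrix) >= 1))
  }

  # monotonicity: final score >= score of the earliest accepted candidate
  first <- tryCatch(select_generator_matrix(1234, 8, 2, search_budget = 1),
                    error = function(e) NULL)
  if (!is.null(first)) expect_gte(g1$score, first$score)

  # Times capacity is enforced
  expect_error(select_generator_matrix(1234, 8, 2, times_capacity = 0),
               "capacity")
})
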