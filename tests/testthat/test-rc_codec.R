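# Segmentation, droplets, equilibrium, strand assembly/parsing, decode.

test_that("bit/base transcoding is the fixed 2-bit map and a bijection", {
  expect_identical(bits_to_bases(c(0, 0, 0, 1, 1, 0, 1, 1)), "ATCG")
  expect_identical(bases_to_bits("ATCG"), c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L))
  expect_identical(bits_to_bases(integer(0)), "")
  expect_identical(bases_to_bits(""), integer(0))
  withr::with_seed(9, {
    for (i in 1:10) {
      bits <- sample(0:1, 2 * sample(1:50, 1), replace = TRUE)
      expect_identical(bases_to_bits(bits_to_bases(bits)), bits)
    }
  })
  expect_error(bits_to_bases(c(1, 0, 1)), "padding")
  expect_error(bases_to_bits("AXG"), "alphabet")
})

test_that("counter fields are big-endian base-4 integers", {
  expect_identical(int_to_bases(0, 6), "AAAAAA")
  expect_identical(int_to_bases(7, 3), "ATG")
  expect_identical(bases_to_int("ATG"), 7)
  for (v in c(0, 1, 63, 4095, 4^6 - 1)) {
    expect_identical(bases_to_int(int_to_bases(v, 6)), v)
  }
  expect_error(int_to_bases(4^3, 3), "capacity")
})

test_that("segmentation yields ceil(bits / chunk_bits) zero-padded chunks", {
  fx <- make_fixture(29390, "random", seed = 2)
  cs <- segment_file(fx$data, 639, bit_length = 29390)
  expect_identical(cs$K, 23L)
  expect_identical(cs$chunk_bits, 1278L)
  expect_identical(cs$original_bit_length, 29390)

  one <- segment_file(as.raw(rep(0xFF, 160)), 639, bit_length = 1278)
  expect_identical(one$K, 1L)
  expect_identical(sum(one$chunks), 1278L)  # no padding

  two <- segment_file(as.raw(rep(0xFF, 160)), 639, bit_length = 1279)
  expect_identical(two$K, 2L)
  expect_identical(sum(two$chunks == 0L), 1277L)  # padding bits are zeros
  expect_error(segment_file(raw(0)), "non-empty")
})

test_that("droplets are row-guided XOR combinations that solve back", {
  cs <- make_chunks(3, 16, seed = 4)
  gen <- structure(list(matrix = rbind(c(0L, 1L, 0L), c(1L, 1L, 0L),
                                       c(1L, 1L, 1L)),
                        seed = 0, attempt_counter = 0, score = 1,
                        K = 3, m = 0),
                   class = "rc_generator")
  dr <- make_droplets(cs, gen)
  expect_identical(dr$payload[1, ], cs$chunks[2, ])
  expect_identical(dr$payload[2, ],
                   as.integer(xor(cs$chunks[1, ], cs$chunks[2, ])))
  expect_identical(dr$row_index, 0:2)
  expect_error(make_droplets(make_chunks(4, 16), gen), "mismatch")

  for (seed in c(10, 20, 30)) {
    K <- 6
    cs <- make_chunks(K, 24, seed = seed)
    gen <- select_generator_matrix(seed, K, 2)
    dr <- make_droplets(cs, gen)
    sol <- solve_augmented(gen$matrix, dr$payload)
    expect_identical(sol$chunks, cs$chunks)
  }
})

test_that("equilibrium masks are involutions and counter 0 means no mask", {
  s <- "ACGTTCGACTGATCGGATCA"
  expect_identical(apply_equilibrium_mask(s, 42, 3, 0), s)
  for (counter in c(1, 2, 17, 4^10 - 1)) {
    masked <- apply_equilibrium_mask(s, 42, 3, counter)
    expect_false(masked == s)
    expect_identical(apply_equilibrium_mask(masked, 42, 3, counter), s)
  }
  # a payload that already passes is returned untouched with counter 0
  pol <- constraint_policy()
  eq <- random_equilibrium(s, 42, 0, pol)
  expect_identical(eq$counter, 0)
  expect_identical(eq$seq, s)
})

test_that("random equilibrium terminates and its output passes the policy", {
  pol <- constraint_policy()
  withr::with_seed(60, {
    for (i in 1:5) {
      pay <- random_dna(120)
      eq <- random_equilibrium(pay, 7, i, pol)
      expect_true(passes_constraints(eq$seq, pol)$pass)
      expect_lt(eq$counter, 4^10)
      # reproducible and invertible via the stored counter
      expect_identical(apply_equilibrium_mask(eq$seq, 7, i, eq$counter), pay)
    }
  })
  # exhaustion is reported when the counter space is tiny (run limit 1 is
  # unsatisfiable at this length, so no mask can ever pass)
  expect_error(random_equilibrium(strrep("A", 200), 7, 0,
                                  constraint_policy(max_homopolymer_run = 1),
                                  counter_capacity = 3),
               "coding-space-exhausted")
})

test_that("the XOR check folds 3-nt words and is linear and sensitive", {
  expect_identical(compute_xor_check(strrep("A", 21)), "AAA")
  seq_xor <- function(a, b) {
    bits_to_bases(as.integer(xor(bases_to_bits(a), bases_to_bits(b))))
  }
  withr::with_seed(70, {
    a <- random_dna(21)
    b <- random_dna(21)
    expect_identical(compute_xor_check(seq_xor(a, b)),
                     seq_xor(compute_xor_check(a), compute_xor_check(b)))
    # every single-base change anywhere in the covered region flips the check
    base_check <- compute_xor_check(a)
    for (pos in 1:21) {
      for (sub in setdiff(c("A", "C", "G", "T"), substr(a, pos, pos))) {
        mutated <- a
        substr(mutated, pos, pos) <- sub
        expect_false(compute_xor_check(mutated) == base_check)
      }
    }
  })
})

test_that("assemble/parse round-trips every field on the compact layout", {
  lay <- test_layout()
  pol <- constraint_policy()
  seed <- seed_from_adapter(default_adapters()[["fwd"]])
  bits <- prng_bits(81, 120)
  out <- assemble_strand(bits, row_index = 3, attempt_counter = 2,
                         seed = seed, layout = lay, policy = pol)
  expect_identical(nchar(out$seq), lay$total)
  expect_true(passes_constraints(out$seq, pol)$pass)

  p <- parse_strand(out$seq, seed, layout = lay)
  expect_true(p$ok)
  expect_identical(p$record$row_index, out$record$row_index)
  expect_identical(p$record$attempt_counter, out$record$attempt_counter)
  expect_identical(p$record$eq_counter, out$record$eq_counter)
  expect_identical(p$record$re_eq_value, out$record$re_eq_value)
  expect_identical(p$record$payload_bits, bits)
})

test_that("parsing rejects corrupted strands with the right reason", {
  lay <- test_layout()
  seed <- seed_from_adapter(default_adapters()[["fwd"]])
  strand <- assemble_strand(prng_bits(82, 120), 1, 0, seed,
                            layout = lay)$seq

  expect_identical(parse_strand("ACGTACGT", seed, layout = lay)$reason,
                   "adapter")
  # single deletion inside the content region -> length
  dele <- paste0(substr(strand, 1, 59), substr(strand, 61, nchar(strand)))
  expect_identical(parse_strand(dele, seed, layout = lay)$reason, "length")
  # single insertion -> length
  ins <- paste0(substr(strand, 1, 59), "A", substr(strand, 60, nchar(strand)))
  expect_identical(parse_strand(ins, seed, layout = lay)$reason, "length")
  # every single substitution in the covered region -> checksum
  inner <- (lay$adapter_nt + 1):(lay$total - lay$adapter_nt)
  withr::with_seed(83, inner <- sample(inner, 25))
  for (pos in inner) {
    for (sub in setdiff(c("A", "C", "G", "T"), substr(strand, pos, pos))) {
      mutated <- strand
      substr(mutated, pos, pos) <- sub
      res <- parse_strand(mutated, seed, layout = lay)
      expect_false(res$ok)
      expect_identical(res$reason, "checksum")
    }
  }
})

test_that("encode/decode round-trips bit-exactly and survives shuffling", {
  lay <- test_layout()
  fx <- make_fixture(900, "random", seed = 31)
  enc <- rc_encode(fx$data, m = 2, layout = lay, bit_length = 900)
  expect_identical(enc$manifest$K, 8L)
  expect_true(all(nchar(enc$strands) == lay$total))
  expect_true(all(grepl("^[ACGT]+$", enc$strands)))
  expect_true(all(vapply(enc$strands,
                         function(s) passes_constraints(s)$pass,
                         logical(1))))

  dec <- rc_decode(enc$strands, enc$manifest)
  expect_identical(dec$data, fx$data)
  expect_true(dec$checksum_ok)
  withr::with_seed(32, shuffled <- sample(enc$strands))
  expect_identical(rc_decode(shuffled, enc$manifest)$data, fx$data)

  # fewer than K usable strands is undecodable by counting
  expect_error(rc_decode(enc$strands[1:7], enc$manifest), "undecodable")
})

test_that("measured erasure tolerance equals the generator's exhaustive score", {
  lay <- test_layout()
  fx <- make_fixture(900, "random", seed = 33)
  enc <- rc_encode(fx$data, m = 2, layout = lay, bit_length = 900)
  K <- enc$manifest$K
  pairs <- combn(K + 2, 2)
  recovered <- apply(pairs, 2, function(drop) {
    d <- tryCatch(rc_decode(enc$strands[-drop], enc$manifest),
                  error = function(e) NULL)
    !is.null(d) && identical(d$data, fx$data)
  })
  expect_equal(mean(recovered), enc$generator$score)
})

test_that("density accounting reproduces the printed figures", {
  d <- density_report(25, 29390)
  expect_identical(d$excl_printed, 1.78)
  expect_identical(d$incl_printed, 1.68)
  z <- density_report(10, 0)
  expect_identical(z$bits_per_nt_incl, 0)
  expect_identical(z$bits_per_nt_excl, 0)
  expect_error(density_report(0, 100), "positive")
})
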