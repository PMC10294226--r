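#' Biological constraint policy
#'
#' Bundles the sequence-screening thresholds applied to every strand before
#' it is considered synthesizable: the maximum tolerated homopolymer run
#' (default 3, i.e. runs of 4+ identical bases fail), the inclusive GC-content
#' window (default 45--55%), and micro-satellite (short tandem repeat)
#' detection limits. Micro-satellite thresholds are not standardized in the
#' DNA-storage literature; the defaults here (repeat unit 2--6 nt, at least 3
#' whole copies spanning at least 9 nt) flag the repeats PCR is known to
#' stutter on while leaving typical random 700-mers mostly clean, and the
#' check can be disabled entirely with `check_microsat = FALSE`.
#'
#' @param max_homopolymer_run longest allowed single-base run.
#' @param gc_min,gc_max inclusive GC-content bounds, as fractions.
#' @param microsat_unit_min,microsat_unit_max repeat-unit lengths screened.
#' @param microsat_min_copies minimum whole copies of the unit.
#' @param microsat_min_span minimum nucleotides covered by the whole copies.
#' @param check_microsat logical: screen for micro-satellites at all.
#' @param screen_adapters logical: include the fixed adapters when screening
#'   an assembled strand.
#' @return an object of class `rc_policy`.
#' @export
constraint_policy <- function(max_homopolymer_run = 3,
                              gc_min = 0.45, gc_max = 0.55,
                              microsat_unit_min = 2, microsat_unit_max = 6,
                              microsat_min_copies = 3, microsat_min_span = 9,
                              check_microsat = TRUE,
                              screen_adapters = TRUE) {
  if (gc_min < 0 || gc_max > 1 || gc_min > gc_max) {
    stop("need 0 <= gc_min <= gc_max <= 1", call. = FALSE)
  }
  if (max_homopolymer_run < 1) stop("max_homopolymer_run must be >= 1",
                                    call. = FALSE)
  if (microsat_unit_min < 2) stop("microsat_unit_min must be >= 2",
                                  call. = FALSE)
  structure(list(max_homopolymer_run = max_homopolymer_run,
                 gc_min = gc_min, gc_max = gc_max,
                 microsat_unit_min = microsat_unit_min,
                 microsat_unit_max = microsat_unit_max,
                 microsat_min_copies = microsat_min_copies,
                 microsat_min_span = microsat_min_span,
                 check_microsat = isTRUE(check_microsat),
                 screen_adapters = isTRUE(screen_adapters)),
            class = "rc_policy")
}

#' GC content of a sequence
#'
#' @param seq non-empty A/C/G/T string.
#' @return fraction of G or C bases, in `[0, 1]`.
#' @examples
#' gc_content("ACGT")  # 0.5
#' @export
gc_content <- function(seq) {
  .check_dna(seq)
  codes <- .base_codes(seq)
  mean(codes >= 2L)  # C=2, G=3
}

#' Longest homopolymer run
#'
#' @inheritParams gc_content
#' @return length of the longest run of identical consecutive bases.
#' @examples
#' max_homopolymer_run("AAAT")  # 3
#' @export
max_homopolymer_run <- function(seq) {
  .check_dna(seq)
  max(rle(.base_codes(seq))$lengths)
}

#' Find micro-satellites (short tandem repeats)
#'
#' Scans for maximal tandem repeats whose unit length lies in
#' `[microsat_unit_min, microsat_unit_max]`, with at least
#' `microsat_min_copies` whole copies spanning at least `microsat_min_span`
#' nucleotides. Only *primitive* units are reported (a unit that is itself a
#' repetition of a shorter unit -- including single-base units, i.e.
#' homopolymers -- is excluded; such regions are reported at their primitive
#' period instead, or left to the homopolymer check). A hit is reported at
#' the leftmost start of its repeat region: the periodicity must not extend
#' even one base to the left.
#'
#' @inheritParams gc_content
#' @param policy an [constraint_policy()] object.
#' @return data frame with columns `start` (1-based), `unit` (the repeat
#'   unit), `copies` (whole copies), `span` (`copies * nchar(unit)`).
#' @examples
#' find_microsatellites("ACACACACAC")  # AC x 5
#' @export
find_microsatellites <- function(seq, policy = constraint_policy()) {
  .check_dna(seq)
  codes <- .base_codes(seq)
  n <- length(codes)
  hits <- list()
  for (u in policy$microsat_unit_min:policy$microsat_unit_max) {
    if (n < 2L * u) next
    match_lag <- codes[seq_len(n - u)] == codes[(u + 1L):n]
    r <- rle(match_lag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k]
      copies <- run_len %/% u + 1L
      span <- copies * u
      if (copies < policy$microsat_min_copies ||
          span < policy$microsat_min_span) next
      start <- starts[k]
      unit <- codes[start:(start + u - 1L)]
      if (!.is_primitive_unit(unit)) next
      hits[[length(hits) + 1L]] <-
        data.frame(start = start, unit = .codes_to_seq(unit),
                   copies = copies, span = span)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), unit = character(),
                      copies = integer(), span = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, nchar(out$unit)), , drop = FALSE]
}

# TRUE unless the unit is an exact repetition of one of its proper divisors.
.is_primitive_unit <- function(unit) {
  u <- length(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && all(unit == rep_len(unit[seq_len(d)], u))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Screen a sequence against the constraint policy
#'
#' @inheritParams find_microsatellites
#' @return list with `pass` (logical) and `reasons` (character vector naming
#'   every failed check: `"homopolymer"`, `"gc"`, `"microsatellite"`).
#' @export
passes_constraints <- function(seq, policy = constraint_policy()) {
  .check_dna(seq)
  reasons <- character()
  if (max_homopolymer_run(seq) > policy$max_homopolymer_run) {
    reasons <- c(reasons, "homopolymer")
  }
  gc <- gc_content(seq)
  if (gc < policy$gc_min || gc > policy$gc_max) {
    reasons <- c(reasons, "gc")
  }
  if (policy$check_microsat &&
      nrow(find_microsatellites(seq, policy)) > 0L) {
    reasons <- c(reasons, "microsatellite")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Feller run-length approximation
#'
#' Classical approximation for the probability that a sequence of `l`
#' Bernoulli(`p`) trials contains no success run of length greater than `m`
#' (for nucleotides, `p = 1/4` is the chance the next base repeats the
#' current one). `feller_x()` is the relevant root of the characteristic
#' equation approximated by its second-order expansion, `feller_beta()` the
#' matching prefactor, and `no_run_prob()` the resulting probability
#' \deqn{q_m(p, l) \approx \beta / x^{l+1}.}
#'
#' @param p success probability, in (0, 1).
#' @param m run-length parameter: runs of length `> m` are the excluded
#'   event.
#' @param l number of trials (sequence length in nt).
#' @param x the root returned by `feller_x()`.
#' @return numeric scalar: `feller_x()` the root (slightly above 1),
#'   `feller_beta()` the prefactor, `no_run_prob()` a probability in
#'   `[0, 1]`.
#' @examples
#' no_run_prob(0.25, 4, 700)  # ~0.126: chance a 700-mer has no run of 5+
#'                            # repeat-successes, i.e. max homopolymer <= 4
#' @export
feller_x <- function(p, m) {
  if (p <= 0 || p >= 1) stop("domain error: p must be in (0, 1)",
                             call. = FALSE)
  if (m < 1) stop("domain error: m must be >= 1", call. = FALSE)
  q <- 1 - p
  1 + q * p^m + (m + 1) * (q * p^m)^2
}

#' @rdname feller_x
#' @export
feller_beta <- function(p, m, x = feller_x(p, m)) {
  if (p <= 0 || p >= 1) stop("domain error: p must be in (0, 1)",
                             call. = FALSE)
  q <- 1 - p
  den <- (m + 1 - m * x) * q
  if (den <= 0) stop("domain error: non-positive denominator", call. = FALSE)
  (1 - p * x) / den
}

#' @rdname feller_x
#' @export
no_run_prob <- function(p, m, l) {
  if (l < 1) stop("domain error: l must be >= 1", call. = FALSE)
  x <- feller_x(p, m)
  b <- feller_beta(p, m, x)
  min(1, max(0, b / x^(l + 1)))
}

#' Strand-level homopolymer compliance probability
#'
#' Probability that a uniform random `l`-nt sequence keeps its longest
#' homopolymer run below `m + ...` -- in the convention used throughout this
#' package, `homopolymer_Q(m, l)` is the Feller estimate of
#' `P(max run <= m - 1)`, computed as the fourth power of the single-base
#' no-run probability at `p = 0.25` ("product of four independent events",
#' one per nucleotide): `no_run_prob(0.25, m, l)^4`. With the defaults
#' `m = 4, l = 700` this gives 2.5e-4 (0.025%), i.e. virtually every random
#' 700-mer contains a run of 4 or more and must be repaired by equilibrium
#' masking rather than discarded.
#'
#' Note the run-length bookkeeping: a run of `r` identical bases contains
#' `r - 1` consecutive repeat-successes at `p = 0.25`, so
#' `no_run_prob(0.25, m, l)` caps the base run length at `m` while the
#' fourth-power strand statistic reproduces the empirical probability of
#' `max run <= m - 1` (cross-checked by simulation in the package tests).
#'
#' @param m run-length parameter (default 4).
#' @param l strand length in nt.
#' @return probability in `[0, 1]`.
#' @examples
#' homopolymer_Q(4, 700)  # ~2.5e-4
#' @export
homopolymer_Q <- function(m, l) {
  if (m < 1) stop("domain error: m must be >= 1", call. = FALSE)
  no_run_prob(0.25, m, l)^4
}

#' Monte-Carlo homopolymer compliance
#'
#' Simulation counterpart of [homopolymer_Q()]: draws `n_seq` uniform random
#' `l`-mers from the package stream and returns the fraction whose longest
#' homopolymer run is at most `max_run`. Runs in compiled code (about 10^6
#' 700-mers per minute-scale budget).
#'
#' @inheritParams prng_state
#' @param n_seq number of simulated sequences.
#' @param l sequence length in nt.
#' @param max_run compliance threshold on the longest run.
#' @return fraction in `[0, 1]`.
#' @export
mc_run_compliance <- function(seed, n_seq, l, max_run) {
  .check_seed(seed)
  .rc_mc_run_compliant(seed, n_seq, as.integer(l), as.integer(max_run))
}

#' Droplet degree density
#'
#' Rows of the random generator matrix have Binomial(K, 1/2) degree, which is
#' approximated by its normal limit: mean `K/2`, variance `K/4`. This is the
#' random-code degree distribution, contrasted with the soliton distributions
#' of LT codes ([ideal_soliton()]).
#'
#' @param x_val point(s) at which to evaluate the density.
#' @param K number of chunks.
#' @return normal density value(s).
#' @export
degree_pdf <- function(x_val, K) {
  if (K < 1) stop("domain error: K must be >= 1", call. = FALSE)
  dnorm(x_val, mean = K / 2, sd = sqrt(K / 4))
}
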