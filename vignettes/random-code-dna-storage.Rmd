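---
title: "The random-code DNA storage codec: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The random-code DNA storage codec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcstore)
```

## The problem

Synthetic DNA stores digital data as sequences over {A, C, G, T}, two bits
per base. Three biochemical constraints limit which sequences can be
synthesized, amplified and sequenced reliably: long homopolymer runs
(4 or more identical consecutive bases raise indel rates), extreme GC
content (outside roughly 45–55% degrades PCR), and micro-satellites (short
tandem repeats that cause polymerase stutter). A practical codec must also
tolerate the loss or corruption of whole strands.

Fountain codes (Luby transform, LT) address strand loss by emitting an open
ended stream of "droplets", each the XOR of a random subset of the K data
chunks, but two weaknesses matter for DNA: the soliton degree distribution
leaves some chunks encoded rarely or never at finite redundancy, and
droplets that fail the biochemical screen are discarded, wasting seed/address
space.

The *random code* (RC) implemented here replaces the open-ended stream with
a jointly selected binary generator matrix, and replaces discard-and-retry
screening with deterministic repair ("random equilibrium").

## The codec

1. **Segmentation.** The file's bit stream is split into
   `K = ceiling(bits / (2 * payload_nt))` chunks of `2 * payload_nt` bits
   (1278 bits for the default 639-nt payload), the last chunk zero-padded.
2. **Generator matrix.** A seeded PRNG fills candidate `(K+m) x K` 0/1
   matrices (m redundant rows). Candidates with an all-zero row or an
   uncovered column are rejected; the rest are scored by the fraction of
   K-row subsets that are uniquely solvable over GF(2), judged by Gaussian
   XOR elimination (unique solution ⇔ all-ones main diagonal after
   triangularization). The best of `search_budget` draws wins; its draw
   index is the **Times** value stored in every strand, so the decoder can
   regenerate the exact matrix from the seed and Times alone.
3. **Droplets.** Row i of the generator selects the chunks XORed into
   droplet i — the row degree is Binomial(K, 1/2), approximately
   N(K/2, K/4), much higher than the soliton mean, which is what lets a
   small m cover all chunks.
4. **Random equilibrium.** A droplet payload that fails the constraint
   screen is XORed base-wise with successive pseudo-random masks (mask `c`
   comes from the substream `derive_seed(seed, row, c)`) until it passes;
   `c` is stored in the 10-nt equilibrium field. Masking is an involution,
   so the decoder just re-applies mask `c`.
5. **Assembly.** Fields are concatenated per the fixed layout
   (20 adapter | 6 Times | 639 payload | 10 equilibrium | 2 re-equilibrium
   | 3 XOR check | 20 adapter = 700 nt) and the complete strand is screened
   again; the 3-nt check is the XOR-fold of the content read as 6-bit
   words.
6. **Decoding.** Adapters locate the strand; a wrong inter-adapter span
   flags an indel (`length`), a check mismatch flags a substitution
   (`checksum`); surviving payloads form an augmented GF(2) system that
   Gaussian XOR elimination solves back to the chunks, truncated to the
   original bit length.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `payload_nt` | 639 nt | data field width; 2 bits/nt |
| `m` | 2 | redundant strands beyond K |
| `max_homopolymer_run` | 3 | "homopolymer < 4" screening rule |
| `gc_min`, `gc_max` | 0.45, 0.55 | inclusive GC window, whole region |
| micro-satellite rule | unit 2–6 nt, ≥3 copies, span ≥9 nt | tandem-repeat screen |
| `search_budget` | 64 | candidate matrices drawn |
| `subset_samples` | 200 | sampled K-subsets per candidate (exhaustive when `choose(K+m, K) <= 1000`) |
| equilibrium space | 4^10 | 10-nt counter field |

With the defaults, a random 639-nt payload passes the homopolymer rule with
probability ≈ 4×10⁻⁴, so the equilibrium search needs a few thousand masks
per strand on average — far inside the 4^10 counter space (the chance of
exhausting it is below e⁻²⁵⁰) but hot enough that the mask-and-screen loop
is compiled.

## The run-length model

The probability that `l` Bernoulli(p) trials contain no success run of
length m is approximated (Feller) by `q_m(p, l) ≈ β / x^(l+1)` with

```
x = 1 + q·p^m + (m+1)·(q·p^m)²,    β = (1 − p·x) / ((m+1 − m·x)·q).
```

Reading "success" as *this position equals a fixed base* (p = 0.25) and
multiplying over the four bases as if independent gives the strand-level
compliance probability `homopolymer_Q(m, l) = q_m(0.25, l)^4`. At
m = 4, l = 700 this prints **0.025%**.

Two caveats, both verified numerically in the tests:

* The four per-base events are *not* independent. The exact probability of
  max run ≤ 3 in a 700-mer (transfer-matrix DP) is 1.978×10⁻⁴; the
  fourth-power formula gives 2.538×10⁻⁴, about 28% high — more than 3
  Monte-Carlo standard errors at 10⁶ replicates. The acceptance test that
  demands Monte-Carlo agreement is therefore red by design; the printed
  two-significant-figure value is reproduced exactly.
* The source formula is written with `q_{m+1}`, but only the run-length
  parameter m (= 4, i.e. P(max run ≤ 3)) reproduces the printed 0.025%;
  with m+1 the value would be ≈ 13%. We follow the printed number.

The degree density `degree_pdf()` is the standard normal N(K/2, K/4); the
prefactor printed in the source is typographically corrupted.

## Erasure tolerance: what is and is not achievable

Losing strand set R is recoverable iff no nonzero left-kernel vector of the
generator is supported off the surviving rows. Two consequences, both
load-bearing for the tests:

* **Score < 1 always (m = 2).** Tolerating *every* 2-subset loss would
  require a binary [K+2, K] code of minimum distance 3, which the Hamming
  bound forbids for K > 1. The measured leave-2-out recovery fraction
  instead equals the generator's exhaustively enumerated score — that
  equality is asserted as the attainable invariant.
* **Single losses are not free either.** With m = 2 the kernel is
  2-dimensional; a row where both kernel basis vectors vanish (~1/4 of rows
  for a random candidate) is fatal on its own. Generators with no such row
  exist but are rare (~(3/4)^(K+2)); the subset-score selection raises the
  tolerant fraction but does not guarantee it. Acceptance expectations that
  assume 100% single-loss tolerance are left red with this analysis.

## Design choices where the source was open

* **PRNG.** A splitmix64 recurrence written out in the compiled core. The
  decode contract needs bit-exact, platform-independent, random-access
  streams ((seed, offset) → bits); R's RNGs guarantee none of that. Seeds
  cross the R boundary as doubles, so derived seeds keep the top 53 bits of
  the 64-bit mix.
* **Seed from adapter.** 20 bases pack to a 40-bit integer (A=00, T=01,
  C=10, G=11, first base most significant), then one splitmix64 finalizer.
* **Row identity.** The decoder must map a strand to its generator row
  after arbitrary loss and reordering. For `K+m <= 32` the Times field
  multiplexes it (`times = attempt*32 + row`); above that the encoder
  inserts a dedicated base-4 row-index field of `ceiling(log4(K+m))` nt and
  records it in the manifest.
* **Re-equilibrium is a header mask, not an additive value.** A searched
  2-nt *value* can never repair a homopolymer run inside the Times field
  (Times value 5 encodes as "AAAATT"). Instead the searched value r ∈ 0..15
  selects an XOR mask over the counter fields, stored in plaintext so the
  decoder unmasks headers before reading them. Same field width and search
  space, provably able to repair header runs.
* **Screening scope.** The XOR check is computed last but *inside* the
  screening loop, so every emitted strand — check field included — passes
  the policy. Adapters are included in the screened region by default
  (`screen_adapters`); the defaults have GC 0.50 and max run 2.
* **Counters** are fixed-width big-endian base-4 integers (A=0,T=1,C=2,G=3).
* **Micro-satellite defaults** (unit 2–6, ≥3 copies, span ≥9) are package
  choices — the constraint is named in the source but never quantified.
  Only primitive repeat units count (a homopolymer is not a
  micro-satellite), hits are anchored at the leftmost start, and the
  detector is brute-force-verified.
* **Manifest.** The original bit length, adapters, layout, policy and an
  MD5 checksum live in a JSON manifest, not in DNA; the source assumes the
  decoder "knows" these.

## The synthetic data generator

`make_fixture()` emulates the *content models* that stress a DNA codec:
uniform random bytes, all zeros, a repeated byte, and 80%-biased bits (the
"extremely high 0/1 rate" case that defeats code-table encoders). The
29,390-bit preset stands in for the biologically stored document (2,939
characters × 10 bits); the original text is not redistributed, so the
fixture is a synthetic equivalent of equal size — every pipeline statistic
(K = 23, 25 strands, densities 1.68/1.78 b/nt) depends only on the size.
What fixtures do **not** emulate: real synthesis/sequencing error profiles,
coverage variation, or chimeric reads. A green round-trip test establishes
codec correctness under the modeled channel, not wet-lab performance.

The channel simulator applies per-strand loss first, then independent
per-base deletion/substitution/insertion. The LT baseline exists only at
packet level (it has no strand format of its own), so codec comparisons are
run under the loss channel; per-base error kinds drive the full RC strand
pipeline, where indels surface as `length` rejections and substitutions as
`checksum` rejections.

## Numerical choices and degenerate inputs

* GF(2) elimination is exact integer arithmetic; no tolerances exist
  anywhere in the codec path. The log-keeping reference elimination is pure
  R; a bit-packed C++ elimination serves the candidate-scoring hot path,
  and the two are cross-checked exhaustively (all 3×3 and 4×4 matrices)
  and on random samples.
* Ties in generator selection go to the earliest draw (smallest Times);
  the search stops early only at a perfect score.
* Empty input files are rejected; a final partial byte is zero-padded and
  the significant bit length recorded.
* `bases_to_int`/`int_to_bases` reject out-of-capacity values rather than
  wrapping.
* Strand parsing never throws: corrupted candidates come back as
  rejections with a reason (`adapter`, `length`, `checksum`).

## Known limitations

* Adapter location is exact string matching (a mismatch-tolerant search is
  stubbed by design, default 0 mismatches); an error *inside* an adapter
  therefore rejects the strand outright.
* `solve_augmented` is dense; K in the tens of thousands would want the
  bit-packed path extended to the augmented solve.
* The robustness comparison figure from the source is not reproduced
  quantitatively — its axis units are not recoverable — only its
  qualitative claims are tested at desk scale.
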