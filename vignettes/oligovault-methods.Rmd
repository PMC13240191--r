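---
title: "Methods: coding, channel model and decoding in oligovault"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coding, channel model and decoding in oligovault}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligovault)
```

oligovault models the information pathway of an electrode-array DNA memory
chip: digital payloads are encoded into addressable oligo designs, the
chip's read channel is simulated with controllable noise, and the decoder
reconstructs the payload while accounting for every loss. This vignette is
the package's own record of the modelling choices, the tunable parameters,
and what the shipped tests do and do not demonstrate.

## The inner code

Each strand payload carries a systematic Reed–Solomon codeword over
GF(2^m). Symbols are integers below 2^m; field arithmetic uses exp/log
tables built from a primitive polynomial whose primitivity is verified
exhaustively at construction (feasible for m ≤ 8). Encoding appends the
remainder of x^(n−k)·m(x) modulo g(x) = ∏_{i=0}^{n−k−1}(x − α^i), so the
first k codeword symbols are the data. Decoding computes syndromes, runs
Berlekamp–Massey for the error locator, finds roots by Chien search over
the n used positions (shortened codes simply use fewer positions), and
solves the syndrome equations for the error values by Gaussian elimination
over the field — a transparent alternative to Forney's formula at the
small t used here.

Two safety rules are absolute:

* a decode whose locator degree, root count and companion checks disagree
  is a *failure*, not a guess;
* every accepted decode is re-encoded and compared to the corrected word.
  Beyond-capacity error patterns can still land on a *different* valid
  codeword — that is intrinsic to bounded-distance decoding at distance
  n−k+1 — but a non-codeword is never returned.

The shipped profiles are `word_rs` = RS(7,3) over GF(8) (t = 2) and
`archive_rs` = RS(25,19) over GF(256) (t = 3). The small code is exercised
exhaustively in the tests: all 512 messages round trip, and every one of
the 1 078 error patterns of weight ≤ 2 on a fixed codeword is corrected.
Parameters live in profiles, not in code, because published descriptions
of such systems rarely pin down (n, k, m) unambiguously; any (n, k, field)
with 0 < k < n ≤ 2^m − 1 can be configured.

## The outer code and the strand architecture

The archive strand is 150 nt: a 20-nt 5' primer, a 10-nt base-4 index, a
100-nt payload region holding exactly one 25-byte RS codeword (19 data
bytes), and a 20-nt 3' primer. The index width was chosen so that the
payload region is a whole number of GF(256) symbols — 100 nt = 200 bits =
25 bytes — while keeping the printed 150/20/20 geometry; a 4^10 address
space is far larger than any pool this package targets, which is the safe
side of the trade-off.

Groups of g data strands (default g = 8, i.e. 12.5% overhead) are closed
by one XOR parity strand, the bytewise exclusive-or of the group. One lost
or undecodable strand per group is recovered exactly; two or more losses
mark the group's data region as lost, filled with a zero-byte sentinel,
and reported — the pipeline never aborts on loss. The byte ranges of lost
regions are part of the decode report so downstream repair knows exactly
what is untrustworthy.

The pixel profile is 90 nt with a 2-nt index and 48-nt payload. Its codec
is a 64-codon-to-6-bit table (codons enumerated lexicographically over
A < C < G < T); the table is a documented, swappable default, standing in
for proprietary codon codes whose tables are unpublished. An image is
split into 8 horizontal bands, one strand per band, mirroring the
eight-pool layout such chips use; this profile relies on consensus alone,
with no inner code, which matches how shallow-index pools are actually
read out.

Words are encoded as: ASCII code points (8-bit, MSB 0) behind a one-byte
length prefix, zero-padded to whole RS(7,3) message blocks (9 bits), each
block RS-encoded to 21 bits, the concatenated bits mapped 2-per-base
(default map 00→A, 01→C, 10→G, 11→T), and the result flanked by two 20-nt
address tokens. The length prefix makes the payload self-describing — the
decoder needs no out-of-band record of word lengths or pad counts.
Sentences are chains in which word i carries tokens (i, i+1), so
consecutive strands overlap at a shared token; assembly concatenates
through each shared token exactly once, the in-silico analogue of assembly
PCR. Token libraries are generated from a seed under three constraints —
pairwise Hamming distance ≥ 8 at length 20, GC between 40 and 60%,
homopolymers capped at 3 — which keeps token identification reliable at
toy scale while staying realistic about primer design.

## Alignment and demultiplexing

Token and primer location use semi-global alignment: the query aligns
end-to-end, the target locally (Biostrings `pairwiseAlignment`, free end
gaps in the target only). Scoring defaults are match +1, mismatch −1, gap
−2, acceptance at 0.8 of the perfect score — for a 20-mer this tolerates
up to two substitutions (score 16) while random 20-mer hits at these
scores are vanishingly rare in toy-scale sequences. Overlapping candidate
hits are resolved best-score-first, ties by leftmost offset, then token
id — a fixed, deterministic order. The tests hold the implementation to an
independent sliding dynamic-programming oracle.

Demultiplexing assigns a read iff both primers score above threshold and
the bases in the index window (immediately after the 5' primer) parse to
an index that exists in the manifest; everything else is unassigned, and
assigned + unassigned always partitions the input. An exact-substring fast
path handles the large majority of reads; only reads with primer-region
errors pay for alignment.

## The read channel

Per-strand read counts are negative binomial with mean `depth_mean`
(default 30) and dispersion `size = 10` — overdispersed counts are the
norm for sequencing coverage, and the family is a parameter, not a
commitment. The mean is scaled by the remaining-copy fraction
10^(−r·n) of the log-linear reuse-degradation model, whose default
parameters (r = 3.1×10⁻⁵ per cycle, N0 = 7.24×10⁶) are the
characterization values of the platform this package models. Crossover
sends each read, with the configured probability, to a uniformly chosen
inactive electrode (the aggregate rates such experiments report do not
constrain the destination distribution, so uniform is the assumption of
least structure). Substitutions, deletions and insertions are applied
independently per base; defaults are 0.3% substitution, 0.15% deletion,
0 insertion — typical short-read magnitudes. Every stochastic property the
tests assert is stated relative to the *configured* rates, not these
defaults. A single seed drives everything; identical inputs and seed give
bit-identical FASTQ.

What the simulator does **not** emulate: position-dependent quality decay,
strand-specific synthesis bias, PCR amplification jackpots, chimeric
reads, homopolymer-length miscalls. Passing tests therefore demonstrate
codec and pipeline correctness under a well-behaved stochastic channel,
not performance on any particular instrument's error profile.

## Consensus and retrieval metrics

Per-index consensus takes the plurality base at each position among reads
whose length equals the designed strand length; ties resolve in the fixed
order A < C < G < T, so consensus is deterministic. Reads of any other
length — deletion or insertion survivors — are excluded from the
positional vote but still count toward depth. That accounting mirrors the
perfect-match-versus-depth metric: a "perfect match" is a read exactly
equal to its designed strand (full-strand equality by default; a
payload-only comparison is available behind the `payload_only` flag, since
reasonable readings of per-index fidelity differ on whether primer errors
should count).

## The modified-IQR repair

When two or more strands of one XOR group are lost, the affected mesh
coordinates are reconstructed from a zero-byte sentinel and are therefore
suspect. The repair rule computes Q1, Q3 and IQR per coordinate axis
(linear-interpolation quantiles, `type = 7` — the stated convention is
"quartiles", and this is the common default convention), flags *flagged*
values outside [Q1 − 0.55·IQR, Q3 + 0.55·IQR], and clamps them to the
violated bound. Only values flagged as unrecovered are candidates — clean
coordinates are never touched, even when extreme. The multiplier 0.55 is
deliberately tighter than the conventional outlier factor 1.5: the flagged
values are already known to be corrupt, so the rule is a repair heuristic,
not an outlier test. Applying the rule per coordinate axis (rather than to
some derived quantity) is this package's documented choice where the
procedure's target series is ambiguous. The bounds are monotone in the
multiplier and the rule degenerates to the identity as k → ∞, both of
which are asserted in the tests.

## Numerical and degenerate-input choices

* Bit streams are zero-padded to symbol/base boundaries; every pad count
  is either recorded (archive manifest) or made unnecessary by
  self-describing framing (word length prefix). Losslessness is explicit,
  never assumed.
* Mesh coordinates are 16-bit signed fixed point with a configurable
  number of fractional bits (default 8: resolution 1/256, range ±128);
  out-of-range coordinates are a quantization error at encode time, not a
  silent wrap.
* A constant copy-number series fits with slope exactly 0 and R² is
  defined as 1 for a zero-variance response (the OLS ratio is 0/0 there).
* An empty read bin, an index with no length-conforming reads, and a
  group with two losses all produce explicit markers (`NA`, `lost`) and
  flow through the pipeline; nothing in the decode path throws on bad
  data, only on malformed configuration.

## Problem sizes in the shipped tests

The test-suite and acceptance-script workloads were sized as the smallest
problems that still exercise every code path meaningfully: exhaustive
sweeps on RS(7,3)/GF(8) (1 078 error patterns; the GF(256) profile is
checked against the same oracle on sampled messages), archives of 10–300
strands, a ~5 KB mesh archive (303 strands) for the noisy-channel
experiment at substitution 0.5%, deletion 0.2%, mean depth 30 over
20 seeded replicates, 200 replicates for decay-slope recovery, and ~10⁵
reads for crossover calibration.

On the degradation experiment, one design decision deserves its rationale:
slope recovery is tested on a 100-point series spanning the projected
100,000-cycle reuse horizon rather than 100 consecutive cycles. This is an
identifiability requirement, not a convenience. With log10 noise
σ = 0.01, the OLS slope standard error over cycles 0–100 is
σ/√Σ(x−x̄)² ≈ 3.4×10⁻⁵ — larger than the slope itself
(3.1×10⁻⁵) — so *no* estimator can recover the slope to 5% from such a
window; sampled across the full horizon the standard error drops by three
orders of magnitude and recovery is routine. Characterizing decay over the
range where it matters is also what the model is for.

## Known limitations

* Bounded-distance RS decoding can miscorrect beyond t errors onto another
  valid codeword; the re-encode check cannot detect that case (no check
  can, without more redundancy).
* The archive's mesh header (vertex/face counts) is not replicated; if
  both strands covering the header region are lost in the same group, the
  mesh cannot be dimensioned and deserializes empty. Callers who need
  header resilience should use a small XOR group size.
* Consensus is positional and length-anchored; it discards indel-bearing
  reads rather than realigning them, trading sensitivity at high indel
  rates for determinism and speed.
* The word decoder reports a payload as unrecovered when any of its RS
  blocks fails; there is no partial-word output.
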