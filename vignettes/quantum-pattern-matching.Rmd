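---
title: "Simulated quantum pattern matching: models, schedules and design choices"
author: "GroverMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated quantum pattern matching: models, schedules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GroverMatch)
```

## The model

GroverMatch simulates, on a classical dense state vector, a quantum
formulation of multiple exact pattern matching over DNA text. The moving
parts, bottom to top:

**Encoding.** The alphabet {A, T, C, G} maps to the two-bit codes
00, 01, 10, 11, so an M-symbol substring is a word of w = 2M bits. A text of
L symbols is padded up to N = 2^n so that the n-qubit address register QA
spans it exactly. Valid occurrence starts live in [0, L − M]; windows that
overhang or fall in the padding are defined (by cyclic wrap, so every
address has a word) but masked out of every match set. Because all four
2-bit codes are real symbols there is no spare "sentinel" code — masking is
the oracle's job, not the encoding's.

**Quantum memory in algebraic normal form.** The address-to-word map is a
truth table with 2^n rows and w Boolean columns. Each column's algebraic
normal form — the XOR of AND-monomials that computes it — is its binary
Möbius transform, computed with the in-place XOR butterfly in O(2^n·n) per
bit and cross-checked in the tests against the O(4^n) pairwise-subset
definition. The load unitary XORs the ANF-evaluated word into the data
register QD, entangling `|i>|word(i)>` for every address component. XOR
loading is a basis permutation: unitary, norm- and QA-marginal-preserving,
and an involution (a second application restores QD to zero, which is
exactly how oracle uncomputation works).

**Exact-match oracle.** An address is marked when its word equals the
pattern bits and the address is a valid start. Two execution modes must
agree and are tested against each other:

- *mask mode* (default above N = 64): the predicate is evaluated
  classically per address and applied as a phase flip on QA — no data
  qubits are simulated;
- *dense mode* (default up to N = 64): QD is physically simulated; the
  memory is loaded, X gates map QD so a match reads all-ones, and the
  marked set is read off the comparator — exercising the load unitary as a
  circuit. The search rounds then apply that mark as phase flips, which is
  the same unitary action on the search register, so dense and mask runs
  produce identical measurement streams under one seed.

**Amplification and scheduling.** One Grover round is a phase flip on the
marked set followed by inversion about the mean on the search register.
With t marked among N, theta = asin(sqrt(t/N)) and the schedule is
r_G = floor(pi/4 · sqrt(N/t)), at least 1 — the measured success
probability after r rounds is exactly sin²((2r+1)·theta), which the engine
reproduces to 1e−9 and the tests verify empirically against a 3-sigma
binomial band.

**Counting.** When t is unknown it is estimated by phase estimation on the
Grover operator, whose eigenphases are ±2·theta. On the two-dimensional
invariant span of (uniform-marked, uniform-unmarked) the operator is a
rotation, and the uniform start state splits equally between the two
eigenvectors, so the phase-register outcome law has a closed form; the
package samples from it directly, which makes counting simulable without
2^(n+r) amplitudes. A dense full-register reference (explicit operator
matrix, accumulated controlled powers, analytic inverse QFT) is kept
internal and the two must agree to 1e−9 in the tests.

**Filtering.** Approximate filtering marks candidate starts from the first
offset of each distinct pattern symbol: every text position holding symbol s
with first offset j marks candidate i − j. Candidates within a
Hamming-distance threshold survive into the location array LA, stored
classically and addressed with tq = ceil(log2 t) qubits. Every exact
occurrence marks its own start and has distance 0, so filtering is complete
at any threshold ≥ 0 — it can only shrink the search space, never lose a
match. The search oracle then dereferences LA and re-checks the exact-match
predicate on the original text.

**Evaluation protocol.** 10 repetitions × 100 iterations of independent
prepare-amplify-measure trials (pooled as 1000), each measurement classified
CIP (a true occurrence index) or IIP, with IMP counting true indices never
measured. Error% = 100·IIP/(CIP+IIP), kept at full precision internally and
printed to one decimal. Since every trial applies the same circuit, the
simulator evolves the state once and samples all trials from the resulting
Born distribution — statistically identical to re-preparing per trial, which
is what the protocol models.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Filtering threshold | ceil(M/4) | symbol substitutions | completeness holds for any value ≥ 0; a small value keeps t ≪ N, which is what makes the filtered register (2n + tq qubits) cheaper than plain addressing |
| Counting runs | 10 | repetitions | majority of 10 with ties to the smaller count; a smaller count under-schedules, which the retry budget recovers, while an overshoot can zero the success amplitude |
| Exact-count precision | n + 2 | qubits | phase resolution pi/2^(n+2) is below half the gap between neighbouring count angles asin(sqrt(k/N)) for all k < 4N/pi², covering the whole small-count regime the search targets; n or n+1 bits provably conflate neighbouring small counts (e.g. t = 10 in N = 128 cannot be read off an r = 7 grid) |
| Approximate-count precision r | caller-chosen, 1 ≤ r < n | qubits | deviates by design; the estimate error is bounded by the resolution envelope N·pi/2^r |
| Retry budget | 3t + 10 | unverified measurements | stochastic misses are possible at any schedule; exhaustion is reported, never silent |
| Protocol size | R = 10, I = 100 | trials | pooled 1000-trial tallies; small I risks IMP > 0 on multi-occurrence patterns, which the tests exercise deliberately |
| Cores C | 1 | emulated instances | round-robin waves of ceil(m/C); parallel cost is the per-wave maximum, summed |

## Design choices where the design was open

- **Enumerating all t occurrences.** After each verified hit the index is
  removed from the marked set and the schedule recomputed with the remaining
  count, making the expected number of productive rounds t rather than
  coupon-collector and keeping total oracle queries within
  O(sqrt(N·t)). Measured indices are always re-verified classically, so
  false positives are structurally impossible; a run that ends with
  matchable indices unfound — whatever the cause, exhausted retries or an
  under-assumed t from approximate counting — is flagged in its report.
- **Majority-marked spaces.** The "at least one iteration" rule is applied
  only for t ≤ N/2. When more than half the space is marked, one forced
  round can annihilate the success amplitude entirely (at t = 3N/4,
  sin²(3·theta) = 0 exactly), deadlocking enumeration; a direct measurement
  of the uniform state already succeeds with probability t/N > 1/2, so the
  schedule there is r_G = 0. This preserves the per-measurement success
  bound P ≥ t/N across the board.
- **Exact-count estimator.** Outcomes y are mapped to counts by snapping
  the implied angle pi·min(y, 2^r − y)/2^r to the nearest achievable
  asin(sqrt(k/N)) rather than rounding N·sin²; at the resolution limit the
  rounding form is biased off the integer grid while angle-snapping is not.
  The approximate variant keeps the plain rounding form, since its defining
  property is the resolution error, not exactness.
- **Location array padding.** When t is not a power of two, LA is padded to
  2^tq with the address N — one past the text, never a valid start — and the
  oracle rejects it on dereference. Padding dilutes the per-measurement
  success probability, which the reports surface rather than hide; a
  filtered space whose marked fraction is near one half is additionally
  flagged as the balanced-oracle regime, where amplification gains little.
- **First-offset marking.** Only the first offset of each distinct pattern
  symbol marks candidates. Using all offsets would enlarge the candidate set
  without affecting completeness, pushing t toward N and eroding the point
  of filtering.
- **Collection loop.** The measure-and-merge candidate collection is
  simulated (batched draws, stopping after 16t + 64 consecutive known
  readings), but the returned LA is defined by the closed-form candidate
  set; a shortfall in the simulated collection sets a `partial` flag and a
  warning instead of changing the contract.

## Numerical conventions

Qubit 0 is the most significant bit of a register's basis index (T0 is the
most significant address variable). Norms are enforced to 1e−9 after every
gate, unitary round-trips hold to 1e−10, and measurement refuses states off
the unit sphere by more than 1e−6. Multi-controlled gates act as direct
amplitude updates; the gate log records logical families {H, X, Rz, CZ, CX}
(diffusion logs its standard H/X/CZ/X/H realization), so logged counts are
this package's own accounting, not a compiler's. Degenerate inputs are
defined, not special-cased away: width-0 registers have one basis value,
t = 0 searches run a budget-bounded schedule and return cleanly, empty
filter results skip the search, and an all-marked space measures uniformly
with zero iterations. Counting majority ties break toward the smaller
count. Derived seeds (one 31-bit stream per core/pattern/run) make every
multi-core result reproducible from the single configuration seed.

## What the synthetic generator does and does not emulate

`generateSyntheticText()` produces uniform-background nucleotide text at
power-of-two-friendly lengths (the study sizes are 128, 256 and 512) with
short patterns planted at known starts (occurrence counts 0–10, matching
the regime in which filtering and counting pay off), verifies every plant
classically before returning, and is deterministic per seed. It does not
emulate genomic composition bias, repeats, ambiguity codes (IUPAC), reverse
complements, or quality-scored reads. Tests passing on these fixtures
certify the algorithmic contracts — oracle equivalence with classical
matching, schedule closed forms, counting accuracy, filtering completeness,
budget accounting — not performance or behaviour on real genomes, where
pattern frequencies and low-complexity regions can push t toward the
balanced regime flagged above.

The tests and the acceptance script size their problems at N ≤ 512 text,
patterns of 1–4 symbols, 1e4-draw empirical bands and 100-fixture sweeps;
these are the package's own reproducibility conditions, and all stochastic
checks run under fixed seeds.

## Known limitations

- Simulation cost is exponential in qubits: dense mode is capped at 24
  qubits, and mask mode's per-address oracle evaluation is linear in N.
- Physical memory-addressing hardware (bucket-brigade switches and their
  qutrit states) is not simulated; the load contract is honoured abstractly.
- Gate counts are logical-family tallies of this simulator, not comparable
  to any particular compiler's decomposition.
- Only power-of-two alphabets are supported (protein alphabets would need
  a 5-bit code with unused patterns); quality scores, IUPAC ambiguity and
  reverse-complement search are out of scope.
- Edit-distance (insertion/deletion) filtering is not implemented; the
  filter's error model is substitution-only Hamming distance.
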