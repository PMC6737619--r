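---
title: "Scoring de novo assemblies against a trusted reference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring de novo assemblies against a trusted reference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffscore)
```

## The problem

Assembly metrics that ignore a reference (N50 and relatives) reward
contiguity even when it is achieved by joining sequence that does not belong
together, while single-aspect reference metrics (genome fraction,
misassembly counts) can disagree with each other across assemblies.
`scaffscore` evaluates an assembly against a trusted reference genome and
consolidates the evidence into one number: every scaffold is scored for how
much of it aligns, how structurally consistent its alignments are, and how
long it is; the assembly score then combines the scaffold-quality
distribution, the reference coverage achieved at each quality level, and the
redundancy of the assembly.

The package deliberately does not align sequences itself. Alignments enter
as PAF (the 12-column pairwise mapping format), produced either by an
external long-sequence mapper or by the built-in synthetic generator, which
emits exact truth alignments. This keeps every downstream stage exactly
testable.

## From raw alignments to a chain

A scaffold typically receives many local alignments, including mutually
redundant and spurious ones. `filter_chain()` retains the subset with
maximum total exact matches subject to a single constraint on the **query
axis**: two retained alignments may overlap by at most `overlap_frac`
(default 0.5) times the shorter alignment's query span, and no retained
alignment may be fully contained in another's query interval.

Two design points matter here:

- **Reference coordinates impose no constraint.** If the filter demanded
  reference-side collinearity, translocations, inversions and relocations —
  exactly the events the penalty must count — would be filtered away before
  they could be seen. Structural inconsistency is judged after filtering,
  never during it.
- **The optimum is exact.** Retained alignments are found as a
  maximum-weight independent set over the pairwise-conflict graph, solved
  per connected component by branch-and-bound with a suffix-weight bound.
  On realistic chains conflicts are sparse and components are tiny, so the
  exact solve costs little; in return, filtering is provably idempotent,
  monotone in added alignments, and equal to brute-force enumeration on
  small instances (a property the test suite checks on random cases).
  Equal-weight ties are broken deterministically: larger query-interval
  union first, then the lexicographically smallest `(q_start, ref_id)`
  sequence.

Residual overlaps within the allowed tolerance are not double counted:
aligned query bases and per-chromosome aligned reference bases are computed
as exact interval unions (`resolve_residual_overlaps()`).

## Misassembly classification

Adjacent alignments in the query-ordered chain are classified with
precedence translocation > inversion > relocation, one event per junction:
different chromosomes make a translocation; same chromosome with opposite
strands makes an inversion; same chromosome and strand makes a relocation
when the separation inconsistency exceeds the threshold `t` (default
1000 bp) in either direction — a gap or an overlap on the reference.

The relocation distance is `d = (reference separation) − (query
separation)`, with the reference separation measured against descending
coordinates for minus-strand pairs. Subtracting the query-side separation is
a deliberate choice: a scaffold joint whose N gap spans exactly the true
genomic distance between its flanking contigs is structurally correct and
should not be penalised, even though its raw reference separation may exceed
`t`. A `query_aware = FALSE` flag restores the literal reference-only
distance for users who want the stricter convention; the two agree whenever
chains are gapless on the query.

## Calibrating expected artifacts

Even a perfect sequence accrues breakpoints when aligned back to its own
genome — repeats, ambiguous regions and aligner heuristics all contribute.
The calibration module quantifies this per reference chromosome: random
fragments tiling each chromosome exactly once (lengths uniform in
[50 kb, 1 Mb] by default, a range that brackets typical contig sizes while
giving the regression length spread), plus the whole chromosome as one more
fragment, are aligned back to the reference; misassemblies are counted for
every relocation threshold on the grid 100, 200, …, 10 000 bp; and the
observations are fit per chromosome by ordinary least squares to

ε = α_c·l + β_c·t + k_c.

All fragments of a chromosome are pooled into one regression. Scoring then
forgives each scaffold `ε_s = max(0, α_c·l_s + β_c·t_u + k_c)` events, where
`c` is the chromosome holding most of the scaffold's aligned bases. The
pair geometry is computed once per fragment and only the relocation calls
are re-evaluated across the 100 thresholds, so calibration cost is dominated
by the alignment, not the counting.

Degenerate cases are handled conservatively: a rank-deficient design (for
example, constant fragment length) falls back to an intercept-only model
with a warning; a chromosome absent from the model contributes ε = 0 — no
artifact credit. In truth-alignment mode (synthetic references) every
fragment aligns perfectly, all observations are zero and the fitted
coefficients are zero; the test suite asserts this self-consistency.

## Scaffold and assembly scores

With `m_s` observed events and `ε_s` expected, the scaffold score is

Q(s) = L(s) · R(s) / (1 + P(s)),

with R(s) the aligned fraction of non-gap bases (clamped at 1 to guard
against any residual double counting), P(s) = log₁₀₀(m_s − ε_s) when the
difference exceeds 1 and 0 otherwise, and L(s) = 1 for scaffolds at least as
long as the shortest reference chromosome θ_G, otherwise
−1/(log₁₀(l_s/θ_G) − 1). The base-100 logarithm sets the penalty scale: 100
unexplained events halve the score. The length factor decays slowly — a
scaffold a tenth of θ_G keeps L = 0.5, a hundredth keeps 1/3 — so
small-to-medium scaffolds are not crushed the way a raw length ratio would.

The assembly score is the geometric mean Q(A) = (Δ_A · Ω_A · Π_A)^(1/3)
of the areas under two cumulative curves and the inverted redundancy.
Numerical conventions, chosen once and used everywhere:

- Curves are evaluated on the 101-point threshold grid 0, 0.01, …, 1, and
  scaffolds with **Q(s) ≥ q** count at threshold q. The closed inequality
  keeps the all-perfect case exact: a perfect assembly has both curves
  identically 1 and areas exactly 1.
- Areas use the trapezoidal rule on that grid, which is exact for these
  step functions up to grid resolution.
- The coverage denominator is the total reference length **including**
  ambiguous bases, which is why a gapped reference scoring itself lands
  slightly below 1 while a gap-free one scores 1 (the self-score test).
- λ_i (the redundancy denominator's per-scaffold term) is measured on the
  reference axis, with within-scaffold overlaps counted once; overlaps
  between scaffolds are precisely the redundancy being measured.
- Unaligned scaffolds score Q = 0 and contribute their length to the Δ_A
  denominator only — the curve's "whole assembly size" reading.

## The synthetic generator

`simulate_assembly()` reproduces four validation designs on a seeded random
toy reference (default 5 chromosomes × 500 kb, GC 0.41), each varying one
property while holding the rest ideal:

| design | varies | held at |
|---|---|---|
| `mean_length` | scaffold mean length (sd = mean/1000) | 1X coverage, no events |
| `misassembly` | planted events per scaffold | 1X, mean 100 kb, sd = mean/1000 |
| `coverage` | sampled fraction of the reference | no events, mean 100 kb, sd = mean |
| `redundancy` | independent 1X samplings concatenated | no events, mean 100 kb, sd = mean/1000 |

The default scaffold mean of 100 kb is about one fifth of the toy
reference's shortest chromosome, matching the scaffold-to-chromosome ratio
of the validation datasets this generator emulates; the sd conventions
(sd = mean/1000, except sd = mean for the coverage design) likewise follow
those designs. Granularity matters at toy scale: with scaffolds a large
fraction of a chromosome, uniform placement is so constrained that extra
coverage buys mostly overlap, and the coverage trend can genuinely invert —
the chosen ratio stays in the regime the scheme is meant for.

Planted misassemblies rebuild a scaffold as k+1 reference segments where
each junction realises exactly one event, drawn uniformly from the three
types. Relocation offsets have magnitude in (t, 10t] — unambiguously above
threshold yet local — sampled from the feasible placement windows; near a
chromosome end, where a long segment may leave no such window, the offset
falls back to any magnitude above t. Scaffold sequences are copied verbatim
from the reference so truth alignments are exact; consequently the
end-to-end identity holds: parsing the truth PAF, filtering, and counting
recovers the planted event count exactly.

What the generator does **not** emulate: sequencing and consensus errors,
real repeat structure, true structural variation between sample and
reference, N-gap placement in scaffolds, and aligner behaviour. Passing
tests therefore demonstrate the correctness of the scoring pipeline on
structurally known input, not robustness to noisy alignments of real data —
for that, the artifact calibration exists, and results will depend on the
chosen aligner.

## Problem sizes and determinism

The test suite and the acceptance script run entirely at desk scale: toy
references of 2–5 chromosomes of 20–500 kb, assemblies up to a few thousand
scaffolds, five replicates per synthetic design level, and brute-force
filtering oracles up to 12 alignments. These sizes were chosen so the exact
oracles (subset enumeration, hand-computed trapezoids) stay feasible while
every scoring regime — short and long scaffolds, partial coverage,
redundancy up to 5X, up to 100 events per scaffold — is exercised.

All randomness flows through explicit integer seeds (`set.seed` at the top
of each generator), so every simulation, calibration and pipeline run is
reproducible; re-running a pipeline configuration writes byte-identical
reports. Partitioning of the assembly for parallel alignment is a
scheduling plan only: results are reduced in scaffold-id order and are
identical for any partition count.

## Known limitations

- Filtering is keep/drop per alignment; it never trims an alignment at a
  conflict boundary, so a long alignment spanning a true breakpoint is kept
  or dropped whole.
- One event is charged per junction with a fixed precedence; a junction
  that is simultaneously, say, inverted and relocated counts once.
- The branch-and-bound solve is exponential in the worst case on dense
  equal-weight conflict components; such inputs do not arise from real
  aligners but can be constructed.
- The artifact model is linear in fragment length and threshold; strongly
  repeat-structured chromosomes may be under- or over-forgiven at the
  extremes of the grid.
- Quality thresholds use a fixed 0.01 grid; scores are not interpolated
  between grid points.
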