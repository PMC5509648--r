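---
title: "Disease-only motif discovery in BCR repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-only motif discovery in BCR repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haystack)
```

## The problem

B-cell receptor (BCR) repertoires sequenced from case and control
cohorts are enormous, diverse, and dominated by germline-templated
structure. A disease-associated signal, if present, may be a short
amino-acid pattern carried by a tiny fraction of sequences in a subset
of patients. `haystack` searches for **disease-only motifs (DOMs)**:
position-specific gapped motifs that match at least a fraction `Dt` of
case subjects while matching *no* control subject.

## The motif model

A motif is an ordered set of components, each an **explicit motif
subsequence** (EMS, a literal run of residues, minimum length three —
the conventional minimum length of a short linear motif) plus an
integer **offset**: the number of residues the component's first
character sits to the *left* of the first CDR3 residue. `(CAR, 0)`
starts on the first CDR3 residue; `(TNE, 14)` starts 14 residues
upstream, inside framework 3. Anchoring to the CDR3 start, rather than
to absolute sequence coordinates, makes components comparable across
sequences of different lengths; negative offsets (positions inside the
CDR3) are allowed, as are components running past the CDR3 end when a
sequence is long enough. A sequence matches a motif if and only if
every occupied position falls inside the sequence and carries exactly
the specified residue; there is no similarity-class or probabilistic
matching.

Canonical form sorts components by decreasing offset and fuses
components that overlap consistently or sit directly adjacent, so a
**gap** always means at least one unspecified position and a motif
with `n + 1` components has exactly `n` gaps. Two operators generate
all motifs from length-3 seeds:

* **EMS extension** appends one residue at a component's N- or C-side
  endpoint (N-side extension increments the offset);
* **cardinality extension** appends a new disjoint, non-adjacent
  atomic (length-3) component, adding one gap.

Both operators, and the merge operation built from them, only add
constraints, so every operator is *anti-monotone* in the match set — a
property the test suite checks on randomized stores, and which the
search exploits when it scores merged motifs inside restricted
sub-repertoires (see below).

## The search

Given a repertoire whose subjects are split into category A (cases,
`|A|` people) and category B (controls, `|B|` people), a motif's match
result is summarized by `a` and `b`, the counts of *distinct* matched
subjects per category (duplicate sequences within one subject cannot
inflate them). Three tunables drive the search:

* `Dt` (default 0.6): DOM threshold; a DOM needs
  `a >= floor(Dt * |A|)` and `b = 0`. The floor (computed with a small
  epsilon guard against floating-point representation of `Dt`) makes
  the integer cutoff consistent with the inequality at non-integer
  `Dt * |A|`.
* `St` (default 15): separation threshold on the score `S = a - b`;
  candidates below `St` are scored and DOM-checked but not expanded.
  A category-blind objective `-(a + b - k)^2` is available for
  sensitivity analyses; `St` must then be set on its (non-positive)
  scale.
* `Gc` (default 2): maximum gaps in any output motif; the traversal
  stops once the frontier's maximum gap count reaches `Gc`.

The traversal is breadth-first over the motif network:

1. **Triplet tally.** All 8,000 possible amino-acid triplets are
   tallied; those contained in fewer than `floor(Dt * |A|)` distinct
   category-A repertoires are dropped. (The threshold is denominated
   in people; a literal raw-occurrence tally is available via
   `tally_mode = "occurrences"` for fidelity experiments.)
2. **Atomic vectors.** Each surviving triplet becomes a
   single-component motif at the offset maximizing `a`; ties go to the
   smallest offset, the most CDR3-proximal and hence most
   biologically anchored choice (any fixed rule would do — this one is
   deterministic).
3. **Non-gapped extension.** Every one-residue extension supported by
   at least one record is scored; survivors of the `St` filter form
   the candidate list `L`.
4. **Recursive restriction.** For each motif `M` in `L`, the records
   matching `M` are copied into a temporary sub-repertoire `dM` that
   *keeps the original cohort denominators*, and steps 1–3 rerun
   inside `dM`.
5. **Merging.** Each non-gapped motif found inside `dM` is folded into
   `M`: overlap-consistent or adjacent components lengthen an EMS,
   disjoint components add a gap; conflicting residues prune the
   candidate.
6. **Iteration.** The merged motifs form the next frontier; the search
   stops when a DOM is found (see stop policies), the frontier
   empties, or the gap bound is reached.

Because a merged motif's constraints contain its parent's, its match
set is exactly the merge piece's match set *inside* `dM`; the
implementation scores merges there rather than rescanning the full
store. The two seed-stage implementations (grouped `data.table`
operations for large stores, vectorized base R for the many small
sub-repertoires) are checked against each other in the tests.

**Traversal count.** `C` counts unique canonical motifs scored against
the full store: every `(triplet, offset)` candidate examined during
atomic-vector generation plus every extension and merged motif. A
visited set keyed on the canonical motif string guarantees nothing is
scored twice; motifs scored only inside a `dM` are considered search
mechanics and enter `C` once their merged form faces the full store.

**Stop policies.** The literal step-6 rule ("stop at the first DOM")
conflicts with reporting many DOMs from one run, so the default
`finish_level` completes the level in which the first DOM appears and
reports everything found by then; `first_dom` and `exhaust` implement
the two extremes. Every reported DOM is re-verified by an independent
`query_motif()` scan before it is returned, and carries a significance
report computed with the run's own `C`.

**Pruning is greedy.** `St` filtering can discard every path to a real
DOM whose individual components separate the cohorts weakly; the test
suite constructs such a cohort (two components, each present in a
different subset of controls, only their conjunction disease-only) and
demonstrates both the recovery at a permissive `St` and the miss at a
strict one. The search is a heuristic, not an exhaustive enumeration.

## Significance: the homogeneous-motif bound

A motif reported as a DOM could in principle be *homogeneous*: equally
likely (probability `p`, unknown) to match any subject of either
category, and disease-only by accident. The probability that such a
motif matches exactly `a` of `|A|` cases and none of `|B|` controls is

$$\binom{|A|}{a} p^a (1-p)^{|A| - a + |B|},$$

which is maximized at `p = w = a / (|A| + |B|)`, giving the closed
form

$$ML(a, |A|, |B|) = \binom{|A|}{a}\,(1-w)^{a(1/w - 1)}\,w^a .$$

The exponent `a(1/w - 1)` equals the integer `|A| + |B| - a` and is
computed exactly as such. Over a search that traversed `C` motifs, the
expected number of spurious homogeneous DOMs with `a` or more case
matches is bounded by

$$Mev = C \sum_{i=a}^{|A|} ML(i, |A|, |B|),$$

exactly linear in `C`. A DOM with `Mev` well below one cannot
plausibly be a traversal artifact; `Mev` is an expected-count bound,
not a p-value, and the package reports it as such.

```{r significance}
mev(2743571, 30, 51, 46)
mev(2743571, 35, 51, 46)
```

Numerics: the fast path evaluates `ML` in log space
(`lchoose` + `log1p`); an independent factored-product path pairs each
binomial factor with a power of `w` so partial products stay in double
range. The two agree to at least ten significant digits across the
full `a` range of a 51/46 cohort, and test constants are frozen from
exact rational arithmetic. The magnitudes involved (binomials near
10^14 against probabilities near 10^-15) are comfortably inside double
range in log space, so no arbitrary-precision arithmetic is needed at
these cohort sizes. With `C = 2,743,571` and a 51/46 cohort the
`-ln(Mev)` curve crosses zero between 17 and 18 case matches — DOMs at
30+ matches sit far above the noise floor.

The maximality of `ML` (that it bounds the exact binomial probability
for *every* `p`) is property-tested against direct computation over a
probability grid for all cohorts up to 12 + 12.

## The synthetic cohort generator

`simulate_repertoire()` exists so every layer above it can be tested
end to end with known ground truth. It emulates germline-templated
IgG-VH amino-acid sequences:

* a fixed IGHV3-flavoured framework template (FR1–FR3, ending
  `...AEDTAVYY`) followed by a CDR3 beginning with the
  germline-templated `CAR`, a uniform-length random CDR3 tail
  (default 10–18 residues), and an FR4 tail (`WGQGTLVTVSS`);
* Poisson-dispersed sequence counts per subject (default mean 500);
* independent per-residue substitution noise (default 0.02,
  a hypermutation-scale rate);
* carriers drawn per subject (default prevalence 0.7 in cases, 0 in
  controls), with the planted motif written into a fraction of each
  carrier's sequences (default 0.05) at its exact CDR3-relative
  offsets *after* the noise, so planted positions are
  mutation-protected and the prevalence parameters are exact ground
  truth. Generation self-checks that every planted record matches.

The default planted motif, `(TNE, 14), (DTA, 6), (CAR, 0)`, is chosen
so that only its `TNE` component differs from the template: `DTA` and
`CAR` are germline-identical, mirroring how a real disease signal can
ride on non-discriminative germline anchors. The default scale — 20 +
20 subjects at ~500 sequences each, roughly 20,000 records — is large
enough to exercise the recursive-restriction machinery and small
enough for minutes-scale continuous testing; carrier fractions keep
the planted signal below 2% of sequences, a realistically sparse
target.

What the generator does *not* emulate, and what passing tests
therefore do not show about real data: nucleotide-level processes
(V(D)J recombination, insertions/deletions, reading-frame shifts),
somatic-hypermutation lineage structure, germline allele diversity
across subjects, and non-uniform CDR3 length/composition
distributions. Recovery of a planted motif demonstrates the search
machinery, not biological discovery power.

At small cohort sizes the generator also demonstrates the flip side of
the significance bound: a reversed-category search over a 10 + 10
cohort at a low DOM threshold happily reports chance conjunctions of
rare CDR3 patterns — all flagged by their own `Mev` far above one.
This is the expected behaviour of a heuristic that scores hundreds of
thousands of candidates, and precisely why `Mev` accompanies every
reported DOM.

The null-cohort experiments in the test suite expose a subtler effect
at the 20 + 20 scale: with hypermutation-scale substitution noise,
individual framework substitutions recur in enough subjects that some,
by chance, concentrate in one category; the separation-guided
traversal then finds anchor conjunctions that exclude the remaining
other-category matches, yielding verified disease-only motifs in
cohorts that contain no signal by construction. Because the traversal
*chooses* which motifs to score based on the data, the `C`-based
multiplicity in `Mev` does not fully cover this selection, and such
artifacts can carry nominally small `Mev` values in small cohorts.
Interpreting DOMs from cohorts of tens of subjects therefore requires
a null/reversed control run — the dual-run design the search is built
around — rather than the `Mev` bound alone.

## Interfaces and conventions

* Input is an AIRR-style rearrangement TSV (`sequence_id`,
  `subject_id`, `diagnosis`, `sequence_aa`, `cdr3_start`, `cdr3_end`;
  coordinates 0-based, half-open), or FASTA plus annotation/metadata
  tables. Sequences containing `X` or other non-standard codes are
  rejected at load and counted: match semantics for ambiguity codes
  are undefined in this model.
* Restriction never changes `|A|` or `|B|`: all thresholds are
  denominated in the original cohort.
* The command-line layer (`haystack simulate / search / match /
  significance`, launcher under `inst/exec/`) is a thin shim over the
  package functions; run configuration files use YAML, a flat and
  diffable format for run records; every run writes a JSON manifest
  with config echo and input digests. Exit codes: 0 success, 2 usage,
  3 data validation, 4 internal invariant breach.

## Problem sizes used by the test suite

Unit tests run on hand-built cohorts of a few dozen records and on
small simulated cohorts (6–12 subjects per arm, 10–60 sequences per
subject). The end-to-end recovery, reversed-category and null-cohort
experiments run at the generator's default study scale (20 + 20
subjects × ~500 sequences), ten seeded recovery cohorts and thirty
silence replicates, with `Dt = 0.6` and `St = 10` — `St` scaled to
this cohort since a 20-subject arm cannot reach a separation of 15
at the planted prevalence of 0.7 (expected carriers: 14). These sizes
were chosen as the smallest at which every search stage, including
recursive restriction and merging, is genuinely exercised.

## Known limitations

* Exact residue matching only; similarity-class matching is out of
  scope.
* The greedy `St` filter can miss DOMs (demonstrated in the tests);
  results are a lower bound on what exists in the data.
* A planted motif carried by fewer than ~one sequence per carrier is
  invisible in expectation; the detection-limit test documents the
  monotone degradation.
* `ML`/`Mev` assume per-subject independence and bound only the
  homogeneous alternative; they say nothing about motifs that are
  genuinely, but weakly, enriched in controls.
* Left-endpoint CDR3 anchoring only; right-endpoint anchoring would
  require a second coordinate convention and is not implemented.
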