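---
title: "Locating tandem repeats in weighted sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating tandem repeats in weighted sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtr)
library(dplyr)
```

## The model

A *weighted sequence* X[1, n] carries, at each position i, a probability
distribution over the characters of an alphabet Σ — a position probability
matrix read as a string. It is the natural summary of a multiple sequence
alignment (each column compressed to its residue frequencies), of
transcription-factor binding profiles, and of any sequence whose residues are
uncertain. A character σ *occurs* at position i when π_i(σ) > 0; only positive
weights are stored.

A plain string f of length p occurs at position i with the *cumulative
weight*

π_i(f) = ∏_{j=1..p} π_{i+j−1}(f[j]),

the product of the per-position character weights along f. Given a threshold
1/k (exposed throughout as `min_prob`), f is a *real factor* at i when
π_i(f) ≥ 1/k. A *tandem repeat* is a triple (i, f, l): l ≥ 2 adjacent,
non-overlapping copies of f, the j-th starting at i + j·p, each copy itself a
real factor. `wtr` solves the all-tandem-repeats problem: report every such
maximal triple for every period 1 ≤ p ≤ ⌊n/2⌋.

Two conventions fix what "every" means here:

* **Per-copy thresholding.** Each copy must individually reach `min_prob`;
  the run's joint probability is never multiplied out. This is forced by the
  definition of an occurrence list: classes only ever hold real-factor
  occurrences, so a run is a chain of qualifying occurrences.
* **Primitivity and maximality.** Only primitive factors (not g^m for m ≥ 2)
  are reported, and only maximal runs: ATATATAT yields (1, AT, 4), never
  (1, ATAT, 2) nor the sub-run (3, AT, 3). Nothing is lost by the primitivity
  filter: each copy of g inside a qualifying copy of f = g^m has weight at
  least that copy's weight (weights are ≤ 1), so the root's run always
  qualifies wherever the power's run would. Rotations such as (2, TA, 3)
  are distinct factors' maximal runs and are reported by default;
  `leftmost_only = TRUE` suppresses runs nested inside an earlier run of the
  same period.

## The partitioning engine

Tandem repeats of all periods are found by iterative refinement of
equivalence classes of occurrence positions. The stage-p state assigns to
each length-p real factor f its class C_f(p): the ordered list of
(position, probability) pairs where f occurs with weight ≥ `min_prob`.
Stage 1 is a single thresholded scan of the stored (position, character,
weight) triples. Stage p + 1 extends every occurrence one character to the
right — the new weight is the old weight times the weight of the appended
character — regroups by the appended character, drops occurrences that fall
below threshold or overrun the sequence end, and prunes classes left with
fewer than two occurrences (a singleton can never again contribute a repeat,
and refinement only shrinks classes).

Unlike the classical partitioning of plain strings, a position here may
belong to up to |Σ| classes per stage, which is exactly why the classical
small-class bookkeeping (and its O(n log n) bound) does not transfer; the
engine instead does work proportional to the total number of surviving
occurrences per stage, O(n²) overall for a bounded alphabet and bounded
ambiguity. When many characters occur at many positions under a permissive
threshold the class count can in principle grow exponentially; the
`max_classes` cap (default 10^6) aborts with a dedicated error instead of
exhausting memory.

### Run detection

Within a class, tandem runs are maximal arithmetic chains of positions with
common difference exactly p. One subtlety is deliberate: chains are tracked
within each residue class of position mod p, not between neighbouring list
entries. In a weighted sequence a factor can occur at positions that overlap
a run's own copies (with both A and B everywhere, AB occurs at 1, 2, 3, …,
yet (1, AB, 2) with copies at 1 and 3 is a genuine repeat), and such
interleaved occurrences must not sever the chain. On plain strings a
primitive factor cannot interleave its own tandem copies (two occurrences
closer than p force a period that divides into a proper root), so there the
residue-class scan and plain adjacent-gap scanning coincide — which is also
why the deterministic reduction test against a naive string scanner is
meaningful. Run detection is a per-class post-pass after each refinement
stage rather than being interleaved with class construction; the cost is the
same single pass over each occurrence list.

## Numerical choices

* Threshold comparisons use `π ≥ min_prob − 1e-12`. The guard keeps
  exact-boundary factors (the worked example's AGA at 0.5 × 1 × 0.6 = 0.3
  against threshold 0.3) from being lost to floating-point products.
* Per-position distributions must sum to 1 within 1e-6 on input and are never
  silently renormalised — downstream thresholds depend on absolute weights,
  so out-of-tolerance input is rejected loudly.
* Incremental class probabilities agree with directly computed cumulative
  weights to 1e-9 (a tested invariant), and the text format round-trips
  weights to the same tolerance.
* Character extension order is lexicographic and reports are sorted by
  (start, period, factor), so output is deterministic byte-for-byte.

## Converting alignments

`msa_to_wseq()` maps an aligned FASTA to a weighted sequence by column
frequency: the weight of c in column i is its count divided by the number of
non-gap symbols in the column. Gaps never enter the alphabet, and an all-gap
column is an error. This is the package's own convention — no pseudocounts,
no renormalisation — chosen because it keeps unanimous columns at weight 1
and keeps the mapping invertible in spirit (frequencies are exactly what the
alignment shows). Users wanting pseudocounts can add them to the tibble
before `weighted_sequence()`.

## The synthetic generator and what tests show

`simulate_wseq()` draws, per position, 1 to `max_chars_per_pos` distinct
characters and a symmetric-Dirichlet weight vector (concentration 1 by
default: flat over the simplex). The defaults — DNA alphabet, at most two
characters per position — emulate profile-like inputs where most positions
are dominated by one residue and a minority are ambiguous.
`plant_tandem_repeat()` overwrites a window so each copy's cumulative weight
is exactly `copy_prob` (each character gets `copy_prob^(1/p)`, residual mass
spread evenly over the other characters), which makes recovery guarantees
exact rather than probabilistic.

The correctness case rests on three independent routes that must agree: the
engine, a brute-force oracle (depth-first enumeration of all real factors
plus a step-p list scan, sharing only the definition of cumulative weight),
and — for deterministic sequences — a naive substring scanner. The test
suite checks engine = oracle exactly on 100 seeded random sequences at three
thresholds (n up to 30), engine = naive scan on 50 random plain strings
(n up to 100), 100% recovery of 50 planted repeats, and the structural
invariants (normalisation, refinement, probability consistency, threshold
monotonicity, primitivity, maximality, non-overlap). A timing sweep at
n ∈ {100, 200, 400, 800} under `min_prob = 0.01` checks that the fitted
runtime exponent stays at most 2.5 — the quadratic contract asymptotically,
without asserting hardware-bound wall-clock values — and that lowering the
threshold never reduces the number of reported repeats. These problem sizes
were chosen to exercise the asymptotics while keeping the default suite
quick.

What the synthetic corpus does *not* emulate: positional dependence
(real profiles correlate neighbouring columns), alphabet-wide ambiguity
(protein profiles routinely carry many low-weight residues per column —
supported, but stressed only up to four characters per position in tests),
and biased repeat content. Passing tests therefore demonstrate algorithmic
correctness on the model's own terms, not calibration against any particular
genome or protein family.

## A worked example

The five-position sequence used throughout the documentation:

```{r}
X <- example_wseq()
X
factor_weight(X, 2, "GAT")
is_real_factor(X, 1, "AGA", min_prob = 0.3)
build_e1(X, min_prob = 0.3)
```

With threshold 0.3 neither surviving class chains at distance 1, and no
longer factor survives with two occurrences, so X has no tandem repeats at
that threshold — as the brute-force oracle confirms:

```{r}
find_tandem_repeats(X, min_prob = 0.3)
nrow(brute_force_tandem_repeats(X, min_prob = 0.3))
```

A deterministic sequence shows the reporting conventions:

```{r}
find_tandem_repeats(wseq_from_string("ATATATAT"), min_prob = 0.5) |>
  glance()
```

## Known limitations

* Exact copies only: no mismatch-tolerant (fuzzy) tandem repeats.
* No IUPAC ambiguity expansion, FASTQ-quality conversion, or smoothing of
  input probabilities — the weights you give are the weights used.
* Permissive thresholds on wide-ambiguity sequences can hit the class cap by
  design; raise `min_prob`, lower `max_period`, or raise `max_classes`
  knowingly.
* Overlapping runs of *different* factors are all reported; no cross-run
  filtering is attempted beyond the optional `leftmost_only` rotation
  suppression.
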