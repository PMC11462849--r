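---
title: "Methods: detecting and quantifying intragenic repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying intragenic repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrarep)
```

## The problem

Genes frequently carry repeated subsequences — tandem duplications,
inverted repeats, decayed copies of older duplications — and the full
repeat structure of a single coding sequence is the object of study here,
not genomic repeats at large. The repeats of interest come in six
overlapping classes: forward and reversed (inverted), perfect and
degenerate, long and short. Established tools each cover a corner of this
space: maximal-exact-repeat finders (the repeat-match family) locate
positions precisely but see only perfect copies; dot-plot comparators (the
dotter family) reveal degenerate similarity visually but attach no
coordinates or statistics to it. `intrarep` implements all three
approaches behind one set of containers, so they can be compared on equal
footing, and adds downstream statistics over the extracted repeat pairs.

## Repeat-pair extraction by iterated local alignment

The core engine is Smith–Waterman local alignment with affine gap costs
(Gotoh's formulation), applied to a sequence against itself (forward
repeats), against its own reverse complement (inverted repeats), or
against a second sequence (cross mode). Dynamic programming is the natural
instrument for this task because it yields degenerate repeats *with
positions and alignments* — exactly what the exact-repeat and dot-matrix
families cannot provide.

A single optimal alignment is not enough: the goal is *every* repeat pair.
The driver therefore iterates: find the best remaining local alignment,
record it if it passes the reporting thresholds, then forbid every matrix
cell on its traceback path (plus a 1-cell neighborhood) and search again,
stopping when the best remaining score falls below `min_score` or
`max_pairs` is reached. Crucially, only matrix *cells* are masked, never
residues: one segment of sequence can take part in many repeat pairs,
which the depth statistics below depend on. A tandem array of k copies is
reported as a covering set of diagonal alignments (one per distinct copy
offset) rather than all k(k−1)/2 copy pairs separately; the masked cells
of an accepted alignment subsume the sub-alignments of the pairs it
covers.

Two cell restrictions shape the self-comparison:

* **Forward self-matrix**: cells with `j − i < min_length` are forbidden.
  This removes the trivial identity diagonal and near-diagonal
  self-overlap, makes every reported pair canonical
  (`start1 < start2`), and still admits immediately adjacent tandem
  copies of length ≥ `min_length`.
* **Reverse self-matrix** (sequence vs its reverse complement): cells
  with `i + j > L` are forbidden, i.e. the first copy must lie strictly
  before the second on the forward strand. This one constraint removes
  mirror-image duplicates and resolves reverse-complement palindromes
  into their two disjoint halves — a full palindrome is reported as its
  first half paired with its second half, the same convention the exact
  finder uses.

Both intervals of a reverse pair are reported on the forward strand; the
second interval's residues are understood to align after
reverse-complementation. Coordinates are 1-based inclusive everywhere on
disk (the convention of the exact-repeat tool family); any 0-based
arithmetic is internal only.

### Scoring parameters

Scoring is identity-based for both alphabets: `match_score` (+1) for
identical unambiguous residues, `mismatch_score` (−1) otherwise.
Ambiguity codes (`N` and the other IUPAC codes; `X`, `B`, `Z`, `*` for
protein) match nothing, including themselves, so identity estimates are
conservative. Protein comparison uses the same identity scoring rather
than a substitution matrix — the toolkit's protein use case is
high-identity containment detection, where identity scoring is exactly
the right instrument — and reverse-complement search is meaningless for
protein, so it is forced off.

Gap costs are affine with `gap_open` −4 and `gap_extend` −2 by default.
This is deliberately stiffer than the weakest workable scheme (−2/−1):
when extending a gap costs no more than a mismatch, optimal local
alignments of *random* nucleotide sequence can accrete long, positive-
scoring gapped excursions, and those excursions glue themselves onto the
ends of genuine repeat alignments, blurring the reported boundaries. With
−4/−2 the alignment of a substitution-diverged repeat (which needs no
gaps) is unaffected, while chance excursions shrink markedly. Real
indel-bearing repeats still align; they simply pay a realistic price per
gap.

Reported pairs must satisfy three thresholds: `min_length` (30 alignment
columns, gaps included, so one number governs both intervals),
`min_identity` (0.45), and `min_score` (15). The identity floor of 0.45
reflects where pairwise sequence similarity stops being distinguishable
from chance at gene scale; all three are exposed on the command line and
in config files.

### End trimming

A local alignment ends, by construction, wherever extension stops paying
— but any positive-scoring chance fluctuation in the flanking sequence
*does* pay, slightly, so raw Smith–Waterman intervals systematically
overshoot the true repeat unit. After traceback, the alignment is
therefore cut to the maximum-sum subarray of its per-column scores
shifted down by the mean column score at `trim_identity` (default 0.55):
terminal stretches whose average identity falls below that level are
stripped, and the pair's spans, score and identity are recomputed from
the trimmed alignment. The default sits just above the effective identity
of gapped chance alignment of random DNA (~0.5) and well below the
divergence levels at which repeat detection is reliable.

The defaults were calibrated on the package's own synthetic ground truth:
two-copy duplications of 200 residues planted in 1 kb random backgrounds
at divergences 0–0.3, ten replicates each. With −2/−1 gaps and no
trimming, 13 of 40 recovered pairs missed the planted intervals at
Jaccard < 0.9 (overshoot up to 80 columns); with −4/−2 and trimming at
0.55 none did, and the mean reported identity per divergence level sat
within 0.03 of the planted value. Two limitations follow directly from
the design. First, a repeat whose overall identity is below
`trim_identity` can be truncated to its densest core or dropped, so users
hunting very low-identity repeats should lower the trim level (0 disables
it) and accept fuzzier boundaries. Second, boundary precision
degrades continuously as the realized identity of a repeat approaches the
trim level — a copy pair at ~0.65 identity has boundary columns that are
statistically indistinguishable from background, and occasional trims of
tens of columns are expected there from any method of this kind.

### Tie-breaking and determinism

Equal-scoring DP cells are resolved toward the later cell in row-major
scan order, which selects the longest of equal-scoring alignments (a
one-substitution copy is reported full-length, not as its longest exact
prefix). In the traceback, diagonal moves are preferred over gaps.
Within the trim step, equal-sum subarrays resolve to the earliest.
Together these make the whole pipeline deterministic: identical inputs
and parameters give byte-identical output files, which the test suite
asserts.

### Complexity

Scores and traceback are O(L²) time and memory per comparison, and the
iterated driver re-runs the DP once per accepted alignment. Inputs above
50 kb are rejected with a pointer to the sliding-window comparator: the
tool targets genes, not genomes. At the scales used throughout the tests
(0.5–2 kb), a full self-comparison takes well under a second.

## Maximal exact repeats

The exact finder plays the repeat-match role. A maximal exact repeat is a
pair of identical (or reverse-complementary) substrings extendable in
neither direction. Forward repeats are found by scanning every diagonal
offset d for maximal runs of positions with `s[i] == s[i+d]` — an O(L²)
scan that is exact, simple to verify, and fast at gene scale, which is
why it was preferred over a suffix-array construction; overlapping copies
(d < length, as in homopolymer runs) are reported, matching repeat-match
behavior. Reverse repeats scan the diagonals of the sequence against its
reverse complement under the same `i + j ≤ L` convention as the aligner:
the kept prefix of each run has the first copy strictly before the
second, which both discards mirror duplicates and splits palindromic runs
at their center. One consequence is worth stating plainly: a
reverse-complement palindrome such as `AAGGCCTT` is reported as its two
halves `(1, 5, 4)`, and short palindromes like `ACGT` yield `(1, 3, 2)` —
the half-split convention is applied uniformly because the containment
guarantee (every perfect aligner pair lies inside some maximal exact
repeat) requires it.

A brute-force oracle (`brute_force_exact_repeats`) enumerates all
position pairs with outward extension under the same reporting policy,
in plain R, guarded to ≤ 2000 residues; the test suite asserts exact
agreement between finder and oracle across seeded random sequences with
and without reverse search, with and without ambiguity codes.

## Sliding-window dot matrix

The dot-matrix comparator emits a point wherever two length-`window`
windows (default 11) match at `threshold` (default 7) or more positions —
a conventional dotter-like operating point; both knobs are exposed.
Points are indexed by window *centers* (window must be odd) with stride
fixed at 1, so that a planted perfect repeat of length ≥ window produces
an unbroken diagonal of points at `threshold == window` exactly where the
aligner reports its pair — a consistency the tests check. Self mode
suppresses the main diagonal and emits canonical points only (forward
`x < y`, reverse `x ≤ y`; a window may pair with its own reverse
complement at a palindrome). Lowering the threshold can only add points.

## Downstream statistics

**Depth.** The depth profile counts, per residue position, how many
repeat-pair interval occurrences cover it, with both intervals of a
self-pair counting separately — each repeated occurrence is an
occurrence. The identity `sum(depth) == Σ (length1 + length2)` holds
exactly and is asserted in the tests.

**Density.** The repeat density index ρ is defined here as the covered
fraction: positions under at least one repeat interval divided by
sequence length. This keeps ρ in [0, 1], makes it comparable across genes
of different lengths, and is monotone under adding pairs; mean depth is
available from the profile for users who prefer an occupancy-weighted
summary. Region-restricted density (e.g. the N-terminal pro-region versus
the catalytic domain of a Type-1 pectin methylesterase CDS) clips pair
intervals to a sub-interval before counting and divides by the region
length.

**Identity histogram.** Pair identities are binned into twenty 0.05-wide
half-open bins `[a, a + 0.05)` with the last bin closed at 1.0, so
perfect repeats land in `[0.95, 1.00]`. Bin indices are computed from
`floor(identity × 20)` with a small epsilon so that ratio-valued
identities falling exactly on an edge (0.65, 0.70, …) open their own bin
despite floating-point representation. The histogram also reports the
modal and rarest non-empty bins.

**Containment.** Cross-mode pairs between a query and a subject support
the fusion-gene/annotation-artifact signature: the query aligning over
(nearly) its whole length inside the subject at high identity. Coverage
is the union of the pairs' query intervals over the query length;
`best_identity` is the identity of the single pair covering the most
query positions, ties toward higher identity. The default call requires
coverage ≥ 0.95 at identity ≥ 1.0 — the strict form of "sequence A is
part of sequence B".

**Density comparison.** Two groups of ρ values are compared with a
two-sided Welch (unequal-variance) two-sample t-test — the robust default
when nothing is known about the group variances. If both groups are
constant the statistic is degenerate; the function then returns p = 1
for equal means and p = 0 otherwise, with a warning, rather than
failing.

## The synthetic-data generator

All quantitative guarantees in the test suite rest on planted ground
truth, so the generator is first-class code. `random_sequence` draws
i.i.d. uniform residues under a fixed seed. `plant_repeats` draws a
template unit, keeps copy 1 verbatim, and independently mutates every
further copy at a per-position substitution probability `divergence`;
substitutions always change the residue (drawn uniformly from the other
3 bases or 19 amino acids), so the expected realized divergence equals
the nominal one and truth assertions can be tight. Copies overwrite the
background at fixed, non-overlapping positions (stable coordinates), and
reverse-oriented copies are written as the reverse complement of their
mutated unit. The truth table records every copy pair with its *realized*
identity from direct positionwise comparison; with `indel_rate > 0`, unit
lengths differ and realized identity comes from a global alignment
instead. All randomness is confined to the stated seed; the session RNG
state is saved and restored.

What the generator does *not* emulate: indel length distributions,
transition/transversion bias, codon structure, GC skew, or the repeat
length/divergence mixtures of real gene families. Passing the planted
tests therefore demonstrates that the algorithms recover what was
planted under clean conditions — it does not certify recall on real
CDSs, where divergence is structured and repeat boundaries are not
crisp.

## Verification conditions and problem sizes

The acceptance-level tests run at desk scale, chosen to exercise every
code path while keeping the whole suite fast: 20 seeded 2 kb sequences
each carrying three planted duplications (lengths 50–200, divergences 0,
0.1, 0.3) for the perfect-pair containment property; 50 seeded sequences
of 50–300 residues (exact finder vs brute-force oracle, both
orientations, minimum length 8 so that results are non-trivial at these
lengths); 200-residue duplications at divergences 0–0.3, ten seeds each,
for recovery fidelity (mean identity within ±0.05 of nominal, intervals
at Jaccard ≥ 0.9); and a 100-residue protein embedded in a 1000-residue
host for containment. `scripts/acceptance.R` recomputes all of these
from scratch under a caller-supplied seed.

## Known limitations

* Quadratic memory bounds practical input to tens of kilobases; the 50 kb
  guard is generous for genes but far from genome scale.
* Identity-based protein scoring will not find diverged protein repeats
  that a BLOSUM-style matrix would; that is outside the toolkit's intent.
* The masking driver reports a covering set for dense tandem arrays, not
  every copy pair individually; downstream depth/density statistics are
  designed around this behavior.
* Repeats with overall identity near or below `trim_identity` have
  imprecise boundaries (see End trimming); boundary uncertainty grows as
  identity falls toward the detection floor.
* The ρ comparison assumes ρ values are approximately exchangeable within
  groups; no multiple-testing correction across gene families is applied.
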