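---
title: "Barcode-anchored alignment of cysteine-rich proteins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-anchored alignment of cysteine-rich proteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysanchor)
```

## The procedure and its assumptions

Cysteine-rich proteins (CRPs) pair very low sequence identity with a
strictly conserved disulphide scaffold. Aligners therefore over-weight the
cysteines — the only letters they can match — and routinely stack
non-homologous ones in a column. The anchored-alignment procedure breaks
that failure mode by making homology explicit *before* alignment:

1. cysteine columns asserted structurally homologous are each replaced by a
   10-residue peptide barcode and the alignment is gap-stripped;
2. the barcoded, unaligned sequences are re-aligned by any standard
   algorithm — every copy of a barcode is (near-)identical, long, and made
   of rare residues, so the aligner has overwhelming incentive to put all
   copies in one column block;
3. each barcode is swapped back for the single character it replaced, the
   block collapses to one column, and the final alignment provably contains
   every original residue with homologous cysteines sharing columns.

The method assumes (i) the homology assertions are correct — they come
from structural superposition, which outlives sequence divergence; (ii)
the chosen barcodes occur nowhere in the input (checked, with automatic
substitution); and (iii) the re-aligner actually co-aligns identical
barcodes. The last assumption is an incentive, not a theorem: a
pathological aligner can split a barcode. The reconstruction stage
therefore verifies span agreement per barcode class and reports — rather
than silently accepting or refusing — any disagreement.

Anchoring is not cysteine-specific: any residue whose homology can be
asserted (e.g. catalytic residues) can be barcoded; the package warns, but
proceeds, when a replaced character is not `C`.

## Barcode design

A good anchor barcode must not align to the input, to random protein
sequence, or to another barcode. The design procedure expresses each
requirement as a measurable filter:

* **Alphabet** `{W, H, M, Y}` — the rarest residues in average protein
  composition (with Y standing in for rare C, which is the residue being
  anchored). Background frequencies are the Swiss-Prot averages bundled as
  `aa_frequencies()` and user-overridable.
* **Composition entropy** `H = -Σ p_a log2(p_a) ≥ 1.8` bits (of 2 possible
  with a 4-letter alphabet). Low-entropy tags such as `WWWWWWWWWW` align
  promiscuously; the threshold keeps compositions near-balanced. The
  curated 8-barcode reference set (`reference_barcode_set()`) contains one
  sequence at 1.761 bits, slightly below this default threshold — the
  generator's own output respects the threshold strictly, and the
  threshold is a config parameter (`entropy_min`) rather than a constant,
  so either convention is expressible.
* **Pairwise Hamming⁺ distance ≥ 4.** Hamming⁺ counts substitutions *and*
  indels; we implement it as standard unit-cost edit (Levenshtein)
  distance, the natural formalisation of "substitutions or indels", via
  `utils::adist`, with an exhaustive recursive oracle validating it in the
  test suite. Plain Hamming distance alone would miss frame-shifted
  near-matches between barcodes.
* **Chance-match probability.** For a barcode `b` of length `k`,
  `P(window) = Π_i f(b_i)` under background frequencies `f`, and
  `P(match) = P(window) × N(L − k + 1)` over an alignment of `N` sequences
  of length `L`. For the reference set the worst case against
  1000 × 1000 input is ≈ 7 × 10⁻¹¹. This is a union bound on expected
  matches, deliberately conservative.

**Set construction** (`generate_default_barcodes()`) is deterministic and
randomness-free: all `alphabet^length` candidates are enumerated in
lexicographic order, entropy-filtered, and admitted greedily — a candidate
joins only if its edit distance to every admitted barcode meets
`distance_min`. Admitted barcodes are then ranked by robustness (minimum
edit distance to the rest of the set, descending), ties broken by entropy
(descending) then lexicographically, and ids `bc.001…` assigned in final
order. The published procedure behind the original default set is not
disclosed, so reproducing that exact list is a non-goal; the set's
*properties* (distance, entropy, determinism) are the contract, and they
are what the tests assert. A greedy scan admits the first ~100 barcodes
after examining ~24 000 candidates (a second or two); the full default
`count = 949` takes under a minute. The implementation screens candidates
with the cheap Hamming lower bound before computing edit distance.

Collision checking (`check_collisions()`) is exact-substring only: the
requirement is that a barcode not *occur* in the input; fuzzy thresholds
would be an invented parameter with no principled value.

## Round-trip bookkeeping

The replaced characters are stored in the FASTA id itself —
`id|CB:column,barcode_id,original;…` — because sequence ids are the one
piece of metadata that essentially every alignment tool preserves
verbatim. The delimiters `|`, `;`, `,` cannot appear in residue alphabets.
The grammar is this package's own (the codec of the original tool is not
published) and is declared normative here; `decode(encode(x)) == x` is
property-tested. Columns are 1-based everywhere a user sees them, matching
how alignment viewers count.

A record with a gap at a barcoded column still receives the barcode and
stores `-` as its original: dropping such records would silently change
the dataset, and omitting the barcode would unanchor the record's other
loops. The case is flagged (`gap_records`) so users can exclude those
sequences deliberately. Reconstruction places the restored character at
the *first* column of each barcode span — deterministic and
order-preserving; when all spans agree the remaining span columns are
all-gap and are removed, so the choice is invisible except under span
disagreement. Span disagreement itself is a warning, not an error: the
method must tolerate imperfect aligners to be usable.

## Homology-class suggestion

From a structure-based alignment, cysteines in the same or a neighbouring
column (±1 by default) are clustered into classes. The sub-3-angstrom
structural-shift criterion is operationalised as column adjacency — the
same proxy the sequence view of a structural alignment affords;
coordinate-level checks would require the structures themselves and are
out of scope. Clustering is greedy left-to-right (seed at the leftmost
unassigned cysteine column, absorb at most one cysteine per record within
the window, nearest first, ties leftward). Chains of adjacency (columns
5, 6, 7 across three records) therefore resolve deterministically in
favour of the leftmost seed; no clustering order is published for the
original, so greedy order is declared normative here. The output is
marked `"suggested"` — confirmation is the user's decision. Sub-group
assignment of structure-less sequences uses the built-in global aligner
score in place of a network BLAST search; an adapter point
(`external_aligner_adapter()`, or simply supplying the user's own
assignments) covers users who prefer BLAST.

## Built-in aligner

`progressive_msa()` exists so the whole round trip is testable with no
external binaries: global affine-gap DP (Gotoh, compiled), gap run cost
`gap_open + (L−1)·gap_extend` with defaults open 10 / extend 1 on
BLOSUM62 (from Biostrings), single-linkage guide clustering on pairwise
scores, profile-profile merges scoring a column pair as the mean
cross-profile pair score (residue-vs-gap = −gap_extend, gap-vs-gap = 0).
Tie-breaking is fixed — diagonal over gap-in-first over gap-in-second —
so output is deterministic for a fixed input order (order-independence is
*not* claimed). The pairwise score is validated against exhaustive
enumeration of all alignments for short sequences. The aligner makes no
claim to production accuracy on non-barcoded sequences; the rare-residue
anchors are what make its output reliable here, and any external aligner
can be substituted via the adapter, which validates that no records or
residues were lost.

## The synthetic family generator

`generate_family()` emulates the two properties that break CRP alignment:
near-total loop divergence and frequent indels around a conserved
scaffold. An ancestor with `n_cysteines` cysteines separated by uniform
random loops (2–12 residues by default) spawns descendants by per-residue
substitution (rate 0.4) and at most one indel per loop (probability 0.5,
length 1–3). Loops never contain cysteine, so the scaffold is unambiguous
and the truth classes are exact. Because mutations are placed by
construction, the generator returns the true alignment and true homology
classes alongside — ground truth no real dataset provides. The default
configuration (20 sequences, 6 cysteines) is the package's benchmark
family; tests use smaller instances (6–10 sequences, 3–5 cysteines) of
the same process.

What the generator does **not** emulate: phylogenetic correlation between
descendants (all are independent draws from the ancestor), realistic
substitution matrices (substitutions are uniform over non-cysteine
residues), length-dependent indel placement, and variable disulphide
connectivity. Passing the end-to-end tests therefore shows the
architecture's guarantee — anchors survive re-alignment and restore
exactly — not that any particular real family will re-align its *loops*
well. Cysteine retention is architecture-guaranteed; loop quality remains
the re-aligner's problem, exactly as with real data.

**Misalignment metric.** For each homology class, members are mapped into
test-alignment columns and compared with the class's modal column (ties
resolved to the lowest column); the rate is
`100 × misaligned / total members`. A modal-column definition is used
because published misalignment percentages come without a counting rule;
the modal rule is the most charitable consistent choice and scores the
true alignment 0 by construction.

## Numerical and degenerate-input choices

* Entropy threshold comparisons use a 10⁻⁹ slack so that exactly-threshold
  compositions (e.g. 1.8 bits) are admitted regardless of floating-point
  representation.
* DP traceback compares scores with 10⁻⁹ tolerance; substitution scores
  are small integers scaled by profile averaging, far above that scale.
* `match_probability` floors the window count at zero (sequences shorter
  than the barcode cannot match).
* An unsatisfiable barcode request (e.g. `distance_min` above the barcode
  length) returns the admissible prefix with a warning, not an error: the
  user asked for a count, the pool answers with what exists.
* Empty loops profile as length 0 with `NA` hydropathy (a mean over
  nothing) and charge 0 (a sum over nothing).
* The RNG is used only inside `generate_family()`, seeded explicitly and
  restored afterwards; no function reads global random state implicitly.

## Benchmark problem sizes

The shipped checks regenerate the first 100 default barcodes (minimum
pairwise edit distance and minimum entropy over the realised set) and run
the full round trip on the 20-sequence, 6-cysteine benchmark family —
sizes chosen so the entire suite re-runs in well under a minute while
still exercising every stage at realistic family scale. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Anchoring requires homology assertions; absent structures (or confident
  predictions), there is nothing to barcode.
* Sequences missing a scaffold cysteine are anchored at a gap; their
  remaining cysteines stay anchored, but the gap-column policy above is a
  modelling choice, flagged per record.
* The built-in aligner is quadratic per pair and intended for
  hundreds, not tens of thousands, of sequences; large jobs should use the
  external-aligner adapter.
* Barcode location after re-alignment is exact-match (gap-tolerant but not
  error-tolerant); an aligner that *edits* residues would surface as a
  missing-barcode error, by design.
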