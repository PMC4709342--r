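# cysanchor

Barcode-anchored multiple sequence alignment for cysteine-rich proteins
(CRPs): defensins, toxins, protease inhibitors and other small
disulphide-stabilised scaffolds.

## The problem

CRP families are notoriously hard to align. Sequence identity within a
family is often below 15 %, the only conserved residues are the cysteines
of the disulphide scaffold, and the inter-cysteine loops gain and lose
residues rapidly. Standard aligners, starved of signal, greedily stack any
cysteines on top of each other, so alignment columns end up mixing
structurally non-homologous cysteines — and every downstream analysis
(phylogeny, loop comparison, engineering) inherits the damage.

## The method

Where protein structures exist, structural superposition says which
cysteines are truly homologous. `cysanchor` turns that knowledge into a
constraint any aligner must respect:

1. **Suggest** — from a structure-based sequence alignment, cluster
   cysteines that sit in the same or a neighbouring column into homology
   classes (`suggest_homologous_cysteine_columns()`); confirming them is
   the one manual step.
2. **Barcode** — replace each confirmed column with a 10-residue peptide
   barcode (`apply_barcodes()`), record the replaced characters in the
   FASTA headers, and strip all gaps so the loops are free to re-align.
3. **Re-align** — with any standard aligner (`external_aligner_adapter()`)
   or the built-in deterministic progressive aligner (`progressive_msa()`).
   The barcodes, being long, mutually distant and made of rare residues,
   are forced into register.
4. **Reconstruct** — swap every barcode back for its original character
   (`reconstruct()`), yielding a final alignment in which homologous
   cysteines are guaranteed to share a column.

Barcodes are built from the four rarest amino acids (W, H, M, Y) and vetted
three ways: composition Shannon entropy `H = -Σ p_a log2 p_a ≥ 1.8` bits
(no repetitive, promiscuously aligning tags), pairwise Hamming⁺ (unit-cost
edit) distance `d ≥ 4` (no barcode aligns to another, even frame-shifted),
and a closed-form chance-match bound
`P(match) = Π_i f(b_i) × N(L − k + 1) ≤ 10⁻¹⁰` for realistic alignment
sizes (no barcode occurs by chance in the input). Barcodes found verbatim
in the input are skipped automatically for the next ranked one.

The package also profiles each inter-cysteine loop (length, mean
Kyte–Doolittle hydropathy, net charge; `loop_profiles()`), ships a
synthetic CRP family generator with exact ground truth for benchmarking
(`generate_family()`), and scores any alignment's cysteine misalignment
against that truth (`misalignment_rate()`).

## Worked example

```r
library(cysanchor)

# a diverged synthetic family with a 6-cysteine scaffold and known truth
fam <- generate_family(family_config(n_sequences = 20, n_cysteines = 6,
                                     seed = 7))
fam$cysteine_columns
#> [1]  27  41  61  79 103 119

# naive alignment of the raw sequences misaligns a fifth of the cysteines
naive <- progressive_msa(list(ids = fam$alignment$ids,
                              seqs = gsub("-", "", fam$alignment$seqs)))
misalignment_rate(naive, fam)
#> [1] 20

# the anchored round trip retains every homologous cysteine
res <- barcode_pipeline(fam$alignment, fam$cysteine_columns)
res
#> reconstruction: 20 records, 6/6 barcode classes aligned
misalignment_rate(res$alignment, fam)
#> [1] 0

# per-loop biophysics of the final alignment
hc <- suggest_homologous_cysteine_columns(res$alignment)
anchors <- vapply(hc$classes, function(cl) cl$column[1], 1L)
prof <- loop_profiles(res$alignment, anchors)
head(prof, 3)
#>   record_id loop_index length hydropathy net_charge
#> 1     seq01          0     14  -0.950000          0
#> 2     seq01          1      7   1.685714         -1
#> 3     seq01          2     10  -2.380000          2
```

A misalignment of 0 % means 100 % of the scaffold cysteines share a column
with their structural homologues; 20 % for the naive route is what the
anchor-free aligner loses on the same data.

A command-line interface over the same functions ships in
`inst/cli/cysanchor` (subcommands `design`, `suggest`, `barcode`,
`reconstruct`, `props`, `simulate`, `roundtrip`); see `?run_cli`.

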