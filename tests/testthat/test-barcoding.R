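toy_barcodes <- function(seqs, ids = sprintf("bc.%03d", seq_along(seqs))) {
  structure(data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE),
            class = c("barcode_set", "data.frame"))
}

test_that("apply_barcodes replaces the column, strips gaps and records originals", {
  aln <- protein_alignment(c("a", "b"), c("ARCDE", "AKC-E"))
  bs <- apply_barcodes(aln, columns = 3,
                       barcodes = toy_barcodes("WWYHWYYHMM", "bc.x"))
  expect_equal(bs$seqs, c("ARWWYHWYYHMMDE", "AKWWYHWYYHMME"))
  expect_equal(unname(bs$assignment$originals[, "3"]), c("C", "C"))
  expect_equal(bs$headers, c("a|CB:3,bc.x,C", "b|CB:3,bc.x,C"))
  expect_equal(unname(bs$assignment$barcode_for_column[["3"]]), "WWYHWYYHMM")
})

test_that("a record with a gap in the barcoded column still gets the barcode", {
  aln <- protein_alignment(c("a", "b"), c("AC-D", "A--D"))
  bs <- suppressWarnings(
    apply_barcodes(aln, 2, barcodes = toy_barcodes("WHMYWHMYWH")))
  expect_equal(bs$seqs[2], "AWHMYWHMYWHD")
  expect_equal(unname(bs$assignment$originals["b", "2"]), "-")
  expect_equal(bs$gap_records, "b")
})

test_that("column validation is 1-based and rejects duplicates", {
  aln <- protein_alignment(c("a", "b"), c("ACDE", "ACDE"))
  expect_error(apply_barcodes(aln, 0), class = "column_range_error")
  expect_error(apply_barcodes(aln, 5), class = "column_range_error")
  expect_error(apply_barcodes(aln, c(2, 2)), class = "duplicate_column_error")
})

test_that("replacing a non-cysteine residue warns but proceeds", {
  aln <- protein_alignment(c("a", "b"), c("AKDE", "AKDE"))
  expect_warning(
    bs <- apply_barcodes(aln, 2, barcodes = toy_barcodes("WHMYWHMYWH")),
    class = "non_cysteine_warning")
  expect_equal(bs$non_cysteine$residue, c("K", "K"))
})

test_that("barcodes appear exactly once, in column order, and residues survive", {
  set.seed(21)
  for (seed in c(3L, 14L, 15L)) {
    fam <- generate_family(family_config(n_sequences = 6, n_cysteines = 4,
                                         seed = seed))
    bs <- apply_barcodes(fam$alignment, fam$cysteine_columns)
    bcs <- bs$assignment$barcode_for_column
    for (i in seq_along(bs$seqs)) {
      s <- bs$seqs[i]
      starts <- vapply(bcs, function(b) {
        hits <- gregexpr(b, s, fixed = TRUE)[[1]]
        expect_length(hits, 1L)       # exactly one occurrence
        hits[1]
      }, numeric(1))
      expect_false(is.unsorted(starts))  # left-to-right in column order
      # excising barcodes and reinserting originals restores the record
      restored <- s
      for (k in seq_along(bcs)) {
        restored <- sub(bcs[k],
                        sub("-", "", bs$assignment$originals[i, k]),
                        restored, fixed = TRUE)
      }
      expect_equal(restored, gsub("-", "", fam$alignment$seqs[i]))
    }
  }
})

test_that("subgroup pooling maps shared classes to shared barcodes", {
  a1 <- protein_alignment(c("a1", "a2"), c("ACDCE", "AC-CE"))
  a2 <- protein_alignment(c("b1", "b2"), c("KCEDC", "KC-DC"))
  pooled <- barcode_subgroup_set(list(
    list(alignment = a1, columns = c(2, 4), labels = c("I", "II")),
    list(alignment = a2, columns = c(2, 5), labels = c("I", "III"))))
  expect_equal(length(pooled$ids), 4L)
  expect_equal(names(pooled$label_map), c("I", "II", "III"))
  # class I carries the identical barcode in both subgroups
  bcI <- pooled$label_map[["I"]]
  expect_true(all(grepl(bcI, pooled$seqs, fixed = TRUE)))
  # class III is absent from subgroup 1's records
  bcIII <- pooled$label_map[["III"]]
  expect_false(any(grepl(bcIII, pooled$seqs[1:2], fixed = TRUE)))
  expect_true(all(grepl(bcIII, pooled$seqs[3:4], fixed = TRUE)))
})

test_that("conflicting explicit label assignments are a merge conflict", {
  a1 <- protein_alignment(c("a1", "a2"), c("ACD", "ACD"))
  expect_error(
    barcode_subgroup_set(
      list(list(alignment = a1, columns = 2, labels = "I")),
      label_barcodes = c(I = "WWYHWYYHMM", I = "WHWMMHYHYY")),
    class = "merge_conflict_error")
  # duplicate ids across subgroups are rejected
  expect_error(
    barcode_subgroup_set(list(
      list(alignment = a1, columns = 2, labels = "I"),
      list(alignment = a1, columns = 2, labels = "I"))),
    class = "duplicate_id_error")
})
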