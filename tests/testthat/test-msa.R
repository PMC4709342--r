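test_that("identity alignment scores the diagonal and adds no gaps", {
  p <- align_params()
  r <- pairwise_align("ACD", "ACD", p)
  expect_equal(r$a_aligned, "ACD")
  expect_equal(r$b_aligned, "ACD")
  expect_equal(r$score,
               sum(diag(p$submat[c("A", "C", "D"), c("A", "C", "D")])))
})

test_that("a forced single indel lands at a deterministic position", {
  r <- pairwise_align("ACD", "AD")
  expect_equal(r$a_aligned, "ACD")
  expect_equal(r$b_aligned, "A-D")
  expect_identical(pairwise_align("ACD", "AD"), r)   # repeatable
  expect_error(pairwise_align("", "AD"), class = "empty_input_error")
})

test_that("alignment never alters residue content", {
  set.seed(7)
  for (i in 1:10) {
    a <- random_peptide(sample(3:12, 1))
    b <- random_peptide(sample(3:12, 1))
    r <- pairwise_align(a, b)
    expect_equal(gsub("-", "", r$a_aligned), a)
    expect_equal(gsub("-", "", r$b_aligned), b)
    expect_equal(nchar(r$a_aligned), nchar(r$b_aligned))
  }
})

test_that("DP score equals exhaustive enumeration for short pairs", {
  p <- align_params()
  # exhaustive over all pairs up to length 3 on a 3-letter alphabet
  strs <- setdiff(all_strings(c("A", "C", "D"), 3L), "")
  for (a in strs[seq(1, length(strs), by = 4)]) for (b in strs) {
    expect_equal(pairwise_align(a, b, p)$score,
                 oracle_best_score(a, b, p$submat, p$gap_open, p$gap_extend),
                 info = paste(a, b))
  }
  # random pairs up to length 6
  set.seed(99)
  for (i in 1:8) {
    a <- random_peptide(sample(4:6, 1))
    b <- random_peptide(sample(4:6, 1))
    expect_equal(pairwise_align(a, b, p)$score,
                 oracle_best_score(a, b, p$submat, p$gap_open, p$gap_extend),
                 info = paste(a, b))
  }
})

test_that("progressive MSA is deterministic and residue-preserving", {
  seqs <- c(s1 = "KRCAADCE", s2 = "KCAAMDCE", s3 = "KRCMDCE", s4 = "RCAADCE")
  aln <- progressive_msa(seqs)
  expect_s3_class(aln, "protein_alignment")
  expect_equal(aln$ids, names(seqs))
  expect_equal(gsub("-", "", aln$seqs), unname(seqs))
  expect_identical(progressive_msa(seqs), aln)

  # identical records align without gaps
  same <- progressive_msa(c(a = "ARNDC", b = "ARNDC", c = "ARNDC"))
  expect_false(any(grepl("-", same$seqs, fixed = TRUE)))

  # single record: passthrough with a note
  expect_message(one <- progressive_msa(c(only = "ARN")), "single")
  expect_equal(one$seqs, "ARN")
})

test_that("barcode blocks co-align across records in progressive MSA", {
  fam <- generate_family(family_config(n_sequences = 8, n_cysteines = 3,
                                       seed = 12))
  bs <- apply_barcodes(fam$alignment, fam$cysteine_columns)
  realigned <- progressive_msa(list(ids = bs$headers, seqs = bs$seqs))
  expected <- lapply(seq_along(bs$ids), function(i)
    stats::setNames(unname(bs$assignment$barcode_for_column),
                    bs$assignment$barcode_ids))
  spans <- locate_barcodes(realigned, expected)
  for (bid in unique(spans$barcode_id)) {
    sp <- spans[spans$barcode_id == bid, ]
    expect_equal(length(unique(sp$start_column)), 1L, info = bid)
    expect_equal(length(unique(sp$end_column)), 1L, info = bid)
  }
})

test_that("the external aligner adapter validates its subprocess output", {
  fam <- generate_family(family_config(n_sequences = 4, n_cysteines = 2,
                                       seed = 2))
  f <- tempfile(fileext = ".fasta")
  write_alignment(fam$alignment, f)

  # a no-op copy of an already-aligned file passes validation
  out <- tempfile(fileext = ".fasta")
  external_aligner_adapter(f, "cp {input} {output}", out)
  expect_equal(read_alignment(out)$seqs, fam$alignment$seqs)

  # losing a record is an error
  expect_error(
    external_aligner_adapter(f, "head -n 2 {input} > {output}", out),
    class = "cysanchor_error")

  # altering residues (shift every residue letter by one) is an error
  expect_error(
    external_aligner_adapter(
      f, "sed 'y/ABCDEFGHIKLMNPQRSTVWY/BCDEFGHIKLMNPQRSTVWYA/' {input} > {output}",
      out),
    class = "residue_mismatch_error")

  expect_error(external_aligner_adapter(f, "cp {input} out.fasta"),
               class = "parameter_error")
  expect_error(
    external_aligner_adapter(f, "false {input} {output}", out),
    class = "aligner_failed_error")
})
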