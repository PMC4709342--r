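test_that("generation is reproducible from the seed and leaves the RNG alone", {
  cfg <- family_config(n_sequences = 5, n_cysteines = 3, seed = 101)
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(f1$classes, f2$classes)

  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_family(cfg)); after <- runif(1)
  expect_identical(before, after)

  expect_error(family_config(loop_length_range = c(9, 2)),
               class = "parameter_error")
  expect_error(family_config(substitution_rate = 1.5),
               class = "parameter_error")
})

test_that("zero mutation rates reproduce the ancestor in every descendant", {
  fam <- generate_family(family_config(n_sequences = 4, n_cysteines = 3,
                                       substitution_rate = 0, indel_rate = 0,
                                       seed = 8))
  expect_equal(length(unique(fam$alignment$seqs)), 1L)
  expect_false(any(grepl("-", fam$alignment$seqs, fixed = TRUE)))
})

test_that("every class is complete when no cysteines are deleted", {
  fam <- generate_family(family_config(n_sequences = 7, n_cysteines = 4,
                                       missing_cysteine_rate = 0, seed = 3))
  for (cl in fam$classes$classes) expect_equal(nrow(cl), 7L)
  # and the scaffold columns really hold cysteines
  m <- do.call(rbind, strsplit(fam$alignment$seqs, ""))
  expect_true(all(m[, fam$cysteine_columns] == "C"))
  # loops never contain cysteine, so the scaffold is unambiguous
  expect_equal(sum(m == "C"), 7L * 4L)
})

test_that("missing cysteines are gapped out and drop from their class", {
  fam <- generate_family(family_config(n_sequences = 12, n_cysteines = 4,
                                       missing_cysteine_rate = 0.3, seed = 4))
  sizes <- vapply(fam$classes$classes, nrow, 1L)
  expect_true(any(sizes < 12L))
  m <- do.call(rbind, strsplit(fam$alignment$seqs, ""))
  for (ci in seq_along(fam$classes$classes)) {
    cl <- fam$classes$classes[[ci]]
    col <- fam$cysteine_columns[ci]
    expect_true(all(m[match(cl$record_id, fam$alignment$ids), col] == "C"))
    absent <- setdiff(fam$alignment$ids, cl$record_id)
    expect_true(all(m[match(absent, fam$alignment$ids), col] == "-"))
  }
})

test_that("the true alignment scores zero misalignment", {
  for (seed in c(1L, 7L, 19L)) {
    fam <- generate_family(family_config(n_sequences = 6, n_cysteines = 4,
                                         seed = seed))
    expect_equal(as.numeric(misalignment_rate(fam$alignment, fam)), 0)
  }
})

test_that("one shifted cysteine among 20 members scores 5 percent", {
  # 10 sequences, 2 complete classes -> 20 members
  fam <- generate_family(family_config(n_sequences = 10, n_cysteines = 2,
                                       substitution_rate = 0, indel_rate = 0,
                                       seed = 5))
  m <- do.call(rbind, strsplit(fam$alignment$seqs, ""))
  col <- fam$cysteine_columns[1]
  # shift record 1's first cysteine right by one column: give record 1 a gap
  # before it, all other records a gap after it
  test <- t(apply(m, 1, function(row) append(row, "-", after = col)))
  test[1, ] <- append(m[1, ], "-", after = col - 1)
  test_aln <- protein_alignment(fam$alignment$ids,
                                apply(test, 1, paste, collapse = ""))
  rate <- misalignment_rate(test_aln, fam)
  expect_equal(as.numeric(rate), 5)
  expect_equal(attr(rate, "n_members"), 20L)
})

test_that("misalignment_rate rejects mismatched records", {
  fam <- generate_family(family_config(n_sequences = 4, n_cysteines = 2,
                                       seed = 6))
  other <- protein_alignment(c("x", "y"), c("ACD", "ACD"))
  expect_error(misalignment_rate(other, fam), class = "input_mismatch_error")
})

test_that("anchored round trip retains all cysteines across a seed sweep", {
  for (seed in c(2L, 11L, 31L)) {
    fam <- generate_family(family_config(n_sequences = 8, n_cysteines = 4,
                                         missing_cysteine_rate = 0,
                                         seed = seed))
    res <- barcode_pipeline(fam$alignment, fam$cysteine_columns)
    expect_equal(as.numeric(misalignment_rate(res$alignment, fam)), 0,
                 info = paste("seed", seed))
  }
})
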