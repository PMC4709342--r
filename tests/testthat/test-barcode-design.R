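test_that("composition entropy matches hand-evaluated values", {
  # reference barcodes: compositions (3,3,2,2)/10 and (5,2,2,1)/10
  expect_equal(shannon_entropy("WWYHWYYHMM"), 1.971, tolerance = 1e-3)
  expect_equal(shannon_entropy("AAAAAAAAAA"), 0)
  expect_equal(shannon_entropy("MYYHHMYWYY"), 1.761, tolerance = 1e-3)
  expect_error(shannon_entropy(""), class = "empty_input_error")
  expect_error(shannon_entropy("AC-D"), class = "invalid_residue_error")
})

test_that("hamming distance counts substitutions position-wise", {
  ref <- reference_barcode_set()
  expect_equal(hamming(ref[["bc.001"]], ref[["bc.002"]]), 7)
  expect_equal(hamming("WHMY", "WHMY"), 0)
  expect_equal(hamming(ref[["bc.003"]], ref[["bc.007"]]), 9)
  expect_error(hamming("AA", "AAA"), class = "length_mismatch_error")
})

test_that("hamming_plus is unit-cost edit distance", {
  expect_equal(hamming_plus("AAA", "AAA"), 0L)
  expect_equal(hamming_plus("AAAA", "AAA"), 1L)
  expect_equal(hamming_plus("", "ABC"), 3L)
  ref <- reference_barcode_set()
  d <- hamming_plus(ref[["bc.001"]], ref[["bc.002"]])
  expect_equal(d, oracle_edit_distance(ref[["bc.001"]], ref[["bc.002"]]))
  expect_lte(d, 7L)
})

test_that("hamming_plus equals the recursive oracle exhaustively (len <= 5, binary alphabet)", {
  strs <- all_strings(c("A", "B"), 5L)
  for (a in strs) for (b in strs) {
    expect_identical(hamming_plus(a, b), oracle_edit_distance(a, b))
  }
})

test_that("both distances behave as metrics; edit distance <= hamming", {
  set.seed(11)
  for (i in 1:40) {
    a <- random_peptide(8L); b <- random_peptide(8L); c <- random_peptide(8L)
    expect_identical(hamming_plus(a, b), hamming_plus(b, a))
    expect_identical(hamming_plus(a, a), 0L)
    expect_lte(hamming_plus(a, c), hamming_plus(a, b) + hamming_plus(b, c))
    expect_lte(hamming_plus(a, b), hamming(a, b))
    expect_equal(hamming(a, b), hamming(b, a))
    expect_lte(hamming(a, c), hamming(a, b) + hamming(b, c))
  }
})

test_that("match probability is the closed-form product times window count", {
  cfg <- barcode_design_config(background_freqs = c(W = 0.011))
  r <- match_probability(strrep("W", 10), cfg,
                         n_sequences = 1, sequence_length = 10)
  expect_equal(r$n_windows, 1L)
  expect_equal(r$per_window_probability, 2.5937e-20, tolerance = 1e-4)
  expect_equal(r$total_probability, r$per_window_probability)

  # degenerate: sequences shorter than the barcode have no windows
  r0 <- match_probability("WWYHWYYHMM", n_sequences = 5, sequence_length = 4)
  expect_equal(r0$n_windows, 0L)
  expect_equal(r0$total_probability, 0)

  expect_error(match_probability("WXZ", n_sequences = 1, sequence_length = 10),
               class = "unknown_residue_error")
})

test_that("reference barcodes respect the published chance-match bound", {
  # the most easily matched of the eight against 1000 sequences x length 1000
  totals <- vapply(reference_barcode_set(), function(b)
    match_probability(b, n_sequences = 1000,
                      sequence_length = 1000)$total_probability, numeric(1))
  expect_equal(unname(totals[["bc.008"]]), 6.86e-11, tolerance = 1e-2)
  expect_lte(max(totals), 1e-10)
})

test_that("match probability scales linearly and favours rarer residues", {
  b <- "WWYHWYYHMM"
  t1 <- match_probability(b, n_sequences = 10, sequence_length = 100)
  t2 <- match_probability(b, n_sequences = 70, sequence_length = 100)
  expect_equal(t2$total_probability / t1$total_probability, 7)
  # swapping a residue for a rarer one cannot increase the probability
  freqs <- aa_frequencies()
  rarer <- "MYYHHMYWYY"               # one Y (0.0292) swapped for W (0.0109)
  swapped <- sub("Y", "W", rarer)
  expect_lte(
    match_probability(swapped, n_sequences = 10,
                      sequence_length = 50)$total_probability,
    match_probability(rarer, n_sequences = 10,
                      sequence_length = 50)$total_probability)
})

test_that("generated barcode sets satisfy the design contract", {
  clear_barcode_cache()
  one <- generate_default_barcodes(barcode_design_config(count = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(nchar(one$sequence), 10L)

  set <- generate_default_barcodes(barcode_design_config(count = 8))
  expect_equal(nrow(set), 8L)
  expect_true(all(nchar(set$sequence) == 10L))
  expect_true(all(strsplit(paste(set$sequence, collapse = ""), "")[[1]] %in%
                    c("W", "H", "M", "Y")))
  d <- utils::adist(set$sequence); diag(d) <- NA
  expect_gte(min(d, na.rm = TRUE), 4L)
  expect_true(all(set$entropy_bits >= 1.8 - 1e-9))
  expect_true(all(shannon_entropy(set$sequence) >= 1.8 - 1e-9))
  # ranking: robustness descending, then entropy descending
  expect_true(all(diff(set$min_distance_to_set) <= 0))
  expect_equal(set$id, sprintf("bc.%03d", 1:8))

  # determinism: regeneration from scratch gives identical output
  clear_barcode_cache()
  again <- generate_default_barcodes(barcode_design_config(count = 8))
  expect_identical(set, again)
})

test_that("an unsatisfiable distance threshold exhausts the pool gracefully", {
  clear_barcode_cache()
  expect_warning(
    small <- generate_default_barcodes(
      barcode_design_config(distance_min = 11, length = 10, count = 5)),
    class = "pool_exhausted_warning")
  expect_lte(nrow(small), 1L)
})

test_that("collision checking substitutes the next suitable barcode", {
  pool <- default_barcodes(4)
  requested <- pool[1, , drop = FALSE]
  # a sequence containing bc.001 verbatim forces a substitution
  rep <- check_collisions(requested,
                          paste0("AAA", pool$sequence[1], "DDD"),
                          pool = pool)
  expect_equal(rep$requested, pool$id[1])
  expect_equal(rep$used, pool$id[2])
  expect_equal(rep$reason, "collision")

  # no collisions: every barcode maps to itself
  clean <- check_collisions(pool, c("ACDEFG", "KLMNPQ"))
  expect_equal(clean$used, pool$id)
  expect_true(all(clean$reason == "ok"))

  # exhaustion: all pool barcodes collide
  expect_error(
    check_collisions(pool[1:2, ], paste(pool$sequence, collapse = "A"),
                     pool = pool[1:2, ]),
    class = "insufficient_barcodes_error")
})
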