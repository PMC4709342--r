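#' Configuration for the synthetic cysteine-rich family generator
#'
#' The generator emulates the hallmark properties of cysteine-rich protein
#' families: a conserved cysteine scaffold, rapidly diverging inter-cysteine
#' loops, and frequent insertions/deletions. The defaults describe the
#' benchmark family used throughout the package's end-to-end tests: 20
#' sequences over a 6-cysteine scaffold with loops of 2-12 residues,
#' heavily diverged (substitution rate 0.4 per loop residue, one indel per
#' loop with probability 0.5).
#'
#' @param n_sequences Number of descendant sequences (>= 2).
#' @param n_cysteines Scaffold size (>= 1).
#' @param loop_length_range Length-2 integer vector, min/max ancestor loop
#'   length in residues.
#' @param substitution_rate Per-residue substitution probability in loops.
#' @param indel_rate Per-loop probability of one insertion or deletion
#'   event (1-3 residues).
#' @param missing_cysteine_rate Per-(sequence, cysteine) probability that a
#'   scaffold cysteine is deleted (gapped out).
#' @param seed Integer seed; the generator never touches the global RNG
#'   state.
#' @return A list of class `family_config`.
#' @export
family_config <- function(n_sequences = 20L, n_cysteines = 6L,
                          loop_length_range = c(2L, 12L),
                          substitution_rate = 0.4, indel_rate = 0.5,
                          missing_cysteine_rate = 0, seed = 1L) {
  n_sequences <- as.integer(n_sequences)
  n_cysteines <- as.integer(n_cysteines)
  loop_length_range <- as.integer(loop_length_range)
  if (n_sequences < 2L) cys_abort("parameter_error", "n_sequences must be >= 2")
  if (n_cysteines < 1L) cys_abort("parameter_error", "n_cysteines must be >= 1")
  if (length(loop_length_range) != 2L ||
      loop_length_range[1L] > loop_length_range[2L] ||
      loop_length_range[1L] < 0L)
    cys_abort("parameter_error",
              "loop_length_range must be c(min, max) with 0 <= min <= max")
  for (r in c(substitution_rate, indel_rate, missing_cysteine_rate))
    if (r < 0 || r > 1)
      cys_abort("parameter_error", "rates must lie in [0, 1]")
  structure(list(n_sequences = n_sequences, n_cysteines = n_cysteines,
                 loop_length_range = loop_length_range,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 missing_cysteine_rate = missing_cysteine_rate,
                 seed = as.integer(seed)),
            class = "family_config")
}

# run code under a private RNG state, restoring the caller's afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic cysteine-rich protein family with known truth
#'
#' Builds an ancestor of `n_cysteines` cysteines separated by random loops
#' (loop residues drawn from the 19 non-cysteine letters, so the scaffold
#' is unambiguous), then derives descendants by per-residue substitutions
#' and per-loop indel events that never touch scaffold cysteines except
#' through `missing_cysteine_rate`, which gap-deletes one. Because every
#' mutation is placed by construction, the true multiple alignment (gaps
#' included) and the true cysteine homology classes are returned alongside,
#' giving pipeline tests an exact ground truth. Fully reproducible from the
#' seed.
#'
#' @param config A [family_config()].
#' @return A list of class `synthetic_family`: `alignment` (the true
#'   [protein_alignment()]), `classes` (a `homology_classes` object with
#'   provenance `"truth"`, columns in true-alignment coordinates),
#'   `cysteine_columns` (integer vector), and `config`.
#' @export
#' @examples
#' fam <- generate_family(family_config(n_sequences = 4, seed = 42))
#' fam$alignment
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  with_seed(config$seed, {
    nseq <- config$n_sequences; ncys <- config$n_cysteines
    aa <- setdiff(AA20, "C")
    # sample() treats a length-1 numeric as 1:n; pick() never does
    pick <- function(x) x[sample.int(length(x), 1L)]
    rand_loop <- function(len) aa[sample.int(length(aa), len, replace = TRUE)]
    anc <- lapply(seq_len(ncys + 1L), function(i)
      rand_loop(pick(config$loop_length_range[1L]:config$loop_length_range[2L])))

    # per (sequence, loop): mutate the ancestor loop, tracking alignment ops
    mutate_loop <- function(loop) {
      len <- length(loop)
      out <- loop
      if (len > 0L) {
        hit <- which(stats::runif(len) < config$substitution_rate)
        for (h in hit) out[h] <- pick(setdiff(aa, out[h]))
      }
      ins_pos <- -1L; ins_res <- character(0); del <- integer(0)
      if (stats::runif(1L) < config$indel_rate) {
        if (len > 0L && stats::runif(1L) < 0.5) {        # deletion
          d <- pick(seq_len(min(3L, len)))
          start <- pick(seq_len(len - d + 1L))
          del <- start:(start + d - 1L)
        } else {                                         # insertion
          d <- pick(1:3)
          ins_pos <- pick(0:len)
          ins_res <- rand_loop(d)
        }
      }
      list(base = out, del = del, ins_pos = ins_pos, ins_res = ins_res)
    }

    loops <- lapply(seq_len(ncys + 1L), function(li)
      lapply(seq_len(nseq), function(si) mutate_loop(anc[[li]])))

    # assemble one aligned block per loop: ancestor columns plus insertion
    # blocks sized to the largest insertion at each boundary position
    loop_block <- function(muts, anc_len) {
      ins_len <- integer(anc_len + 1L)        # boundary positions 0..len
      for (mu in muts) if (mu$ins_pos >= 0L)
        ins_len[mu$ins_pos + 1L] <- max(ins_len[mu$ins_pos + 1L],
                                        length(mu$ins_res))
      width <- anc_len + sum(ins_len)
      block <- matrix("-", length(muts), max(width, 0L))
      for (si in seq_along(muts)) {
        mu <- muts[[si]]
        col <- 0L
        for (p in 0:anc_len) {
          if (ins_len[p + 1L] > 0L) {
            if (mu$ins_pos == p) {
              k <- length(mu$ins_res)
              if (k) block[si, col + seq_len(k)] <- mu$ins_res
            }
            col <- col + ins_len[p + 1L]
          }
          if (p < anc_len) {
            col <- col + 1L
            block[si, col] <- if ((p + 1L) %in% mu$del) "-" else mu$base[p + 1L]
          }
        }
      }
      block
    }

    nseq_ids <- sprintf("seq%02d", seq_len(nseq))
    blocks <- list(); cys_cols <- integer(0); width <- 0L
    present <- matrix(TRUE, nseq, ncys)
    for (li in seq_len(ncys + 1L)) {
      b <- loop_block(loops[[li]], length(anc[[li]]))
      blocks[[length(blocks) + 1L]] <- b
      width <- width + ncol(b)
      if (li <= ncys) {
        keep <- stats::runif(nseq) >= config$missing_cysteine_rate
        present[, li] <- keep
        cys <- matrix(ifelse(keep, "C", "-"), nseq, 1L)
        blocks[[length(blocks) + 1L]] <- cys
        width <- width + 1L
        cys_cols <- c(cys_cols, width)
      }
    }
    m <- do.call(cbind, blocks)
    # drop all-gap columns (possible when a whole loop is deleted everywhere)
    keep_col <- colSums(m != "-") > 0L
    cys_cols <- vapply(cys_cols, function(cc) sum(keep_col[seq_len(cc)]),
                       integer(1))
    m <- m[, keep_col, drop = FALSE]
    rownames(m) <- nseq_ids
    aln <- matrix_to_alignment(m)

    classes <- lapply(seq_len(ncys), function(ci) {
      who <- which(present[, ci])
      data.frame(record_id = nseq_ids[who],
                 column = rep(cys_cols[ci], length(who)),
                 stringsAsFactors = FALSE)
    })
    names(classes) <- as.character(utils::as.roman(seq_len(ncys)))
    structure(list(
      alignment = aln,
      classes = structure(list(classes = classes, provenance = "truth",
                               residue = "C", neighbour_window = 0L),
                          class = "homology_classes"),
      cysteine_columns = cys_cols,
      config = config),
      class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf(
    "synthetic_family: %d sequences, %d-cysteine scaffold (columns %s), seed %d\n",
    x$config$n_sequences, x$config$n_cysteines,
    paste(x$cysteine_columns, collapse = ","), x$config$seed))
  invisible(x)
}

#' Cysteine misalignment rate of a test alignment against known truth
#'
#' For each homology class, each member position is mapped from
#' truth (reference-alignment) coordinates to its residue ordinal, located
#' in the test alignment, and compared with the class's modal test column.
#' A member outside the modal column is misaligned; the rate is
#' `100 * misaligned / total members`. The true alignment itself always
#' scores 0; a perfectly anchored pipeline retains 100 % of homologous
#' cysteines in shared columns, i.e. also scores 0.
#'
#' @param test_alignment A [protein_alignment()] of the same records
#'   (identical ids and gap-stripped sequences) as the truth.
#' @param truth A `synthetic_family`, or a `homology_classes` object (then
#'   `reference` is required).
#' @param reference The [protein_alignment()] whose coordinates the truth
#'   columns refer to; taken from `truth` when it is a `synthetic_family`.
#' @return Percentage in `[0, 100]`, with attribute `"n_members"`.
#' @export
misalignment_rate <- function(test_alignment, truth, reference = NULL) {
  stopifnot(inherits(test_alignment, "protein_alignment"))
  if (inherits(truth, "synthetic_family")) {
    reference <- truth$alignment
    truth <- truth$classes
  }
  if (is.null(reference))
    cys_abort("parameter_error",
              "reference alignment required when truth is a class set")
  idx <- match(reference$ids, test_alignment$ids)
  if (anyNA(idx))
    cys_abort("input_mismatch_error", sprintf(
      "record(s) missing from test alignment: %s",
      paste(reference$ids[is.na(idx)], collapse = ", ")))
  if (!identical(strip_gaps(test_alignment$seqs[idx]),
                 strip_gaps(reference$seqs)))
    cys_abort("input_mismatch_error",
              "test alignment residues differ from the reference records")
  ref_m <- alignment_matrix(reference)
  test_m <- alignment_matrix(test_alignment)
  # residue ordinal -> test column lookup per record
  test_cols <- lapply(rownames(ref_m), function(id)
    which(test_m[id, ] != "-"))
  names(test_cols) <- rownames(ref_m)

  total <- 0L; missed <- 0L
  for (cl in truth$classes) {
    if (!nrow(cl)) next
    cols <- vapply(seq_len(nrow(cl)), function(r) {
      id <- cl$record_id[r]
      ordinal <- sum(ref_m[id, seq_len(cl$column[r])] != "-")
      test_cols[[id]][ordinal]
    }, integer(1))
    counts <- table(cols)
    modal <- min(as.integer(names(counts)[counts == max(counts)]))
    total <- total + length(cols)
    missed <- missed + sum(cols != modal)
  }
  if (total == 0L)
    cys_abort("empty_input_error", "truth contains no class members")
  structure(100 * missed / total, n_members = total)
}
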