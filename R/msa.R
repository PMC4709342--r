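#' Alignment scoring parameters
#'
#' Scoring used by the built-in aligner: a named substitution matrix
#' (BLOSUM62, taken from Biostrings' bundled matrices) and affine gap
#' penalties where a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`. The rare-residue barcodes make anchor
#' alignment robust to the precise values; the defaults (open 10, extend 1)
#' are conventional for protein alignment.
#'
#' @param matrix Substitution matrix name available from Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`), or a numeric matrix with
#'   residue row/column names.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  if (gap_open < 0 || gap_extend < 0)
    cys_abort("parameter_error", "gap penalties must be >= 0")
  if (is.character(matrix)) {
    key <- paste0("submat_", matrix)
    if (is.null(.cys_cache[[key]])) {
      e <- new.env()
      ok <- tryCatch({
        utils::data(list = matrix, package = "Biostrings", envir = e)
        TRUE
      }, warning = function(w) FALSE, error = function(e) FALSE)
      if (!ok || !exists(matrix, envir = e))
        cys_abort("parameter_error",
                  sprintf("unknown substitution matrix '%s'", matrix))
      .cys_cache[[key]] <- get(matrix, envir = e)
    }
    m <- .cys_cache[[key]]
  } else {
    m <- matrix
  }
  if (!is.matrix(m) || is.null(rownames(m)) ||
      !all(AA20 %in% rownames(m)) || !identical(rownames(m), colnames(m)))
    cys_abort("parameter_error",
              "substitution matrix must cover the 20 residues, rows == cols")
  structure(list(submat = m, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# encode gapped sequences into an integer profile matrix
# (0 = gap, k = index into substitution alphabet)
encode_profile <- function(seqs, alphabet) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  len <- unique(lengths(chars))
  if (length(len) != 1L)
    cys_abort("alignment_shape_error", "profile sequences differ in length")
  m <- matrix(0L, length(seqs), len)
  for (i in seq_along(chars)) {
    code <- match(chars[[i]], alphabet)
    code[chars[[i]] == "-"] <- 0L
    if (anyNA(code))
      cys_abort("unknown_residue_error", sprintf(
        "residue '%s' not covered by the substitution matrix",
        chars[[i]][is.na(code)][1L]))
    m[i, ] <- code
  }
  m
}

decode_profile <- function(m, alphabet) {
  apply(m, 1L, function(code) {
    out <- rep("-", length(code))
    out[code > 0L] <- alphabet[code[code > 0L]]
    paste(out, collapse = "")
  })
}

# apply traceback moves to a pair of profiles, inserting gap columns
merge_profiles <- function(A, B, moves) {
  ncolumns <- length(moves)
  out <- matrix(0L, nrow(A) + nrow(B), ncolumns)
  ia <- 0L; ib <- 0L
  for (k in seq_along(moves)) {
    mv <- moves[k]
    if (mv == 0L) {
      ia <- ia + 1L; ib <- ib + 1L
      out[, k] <- c(A[, ia], B[, ib])
    } else if (mv == 1L) {             # gap column in A
      ib <- ib + 1L
      out[, k] <- c(rep(0L, nrow(A)), B[, ib])
    } else {                           # gap column in B
      ia <- ia + 1L
      out[, k] <- c(A[, ia], rep(0L, nrow(B)))
    }
  }
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh's three-state
#' dynamic programme, compiled). Tie-breaking is deterministic: on equal
#' score a match/mismatch column is preferred over a gap in the first
#' sequence, which is preferred over a gap in the second.
#'
#' @param a,b Gap-free sequences.
#' @param params An [align_params()].
#' @return A list with `a_aligned`, `b_aligned` (equal-length gapped
#'   strings) and `score`.
#' @export
#' @examples
#' pairwise_align("ACD", "AD")
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b))
    cys_abort("empty_input_error", "pairwise_align needs non-empty sequences")
  alphabet <- rownames(params$submat)
  A <- encode_profile(a, alphabet)
  B <- encode_profile(b, alphabet)
  res <- .align_profiles_cpp(A, B, params$submat,
                             params$gap_open, params$gap_extend)
  merged <- merge_profiles(A, B, res$moves)
  seqs <- decode_profile(merged, alphabet)
  list(a_aligned = seqs[1L], b_aligned = seqs[2L], score = res$score)
}

#' Progressive multiple sequence alignment
#'
#' A minimal deterministic progressive aligner: all pairwise alignment
#' scores are computed, a single-linkage guide clustering orders the merges,
#' and profiles are aligned profile-to-profile with the same affine-gap DP
#' (column score = mean cross-profile pair score). Intended to make the
#' barcode round trip self-contained; for production alignments use
#' [external_aligner_adapter()] with a dedicated tool.
#'
#' @param records A list with `ids` and `seqs` (gap-free), e.g. from
#'   [read_sequences()], or a character vector of sequences (optionally
#'   named).
#' @param params An [align_params()].
#' @return A [protein_alignment()] in the input row order.
#' @export
progressive_msa <- function(records, params = align_params()) {
  if (is.character(records)) {
    ids <- names(records) %||% sprintf("seq%d", seq_along(records))
    records <- list(ids = ids, seqs = unname(records))
  }
  ids <- records$ids; seqs <- strip_gaps(records$seqs)
  n <- length(ids)
  if (n == 0L) cys_abort("empty_input_error", "no sequences to align")
  if (n == 1L) {
    message("single sequence: returned unchanged")
    return(structure(list(ids = ids, seqs = seqs,
                          desc = rep("", 1L), ncol = nchar(seqs)),
                     class = "protein_alignment"))
  }
  alphabet <- rownames(params$submat)
  profiles <- lapply(seq_len(n), function(i) {
    p <- encode_profile(seqs[i], alphabet)
    rownames(p) <- ids[i]
    p
  })
  # guide order: single linkage on (max score - score)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- .align_profiles_cpp(profiles[[i]], profiles[[j]], params$submat,
                               params$gap_open, params$gap_extend)
      score[i, j] <- score[j, i] <- r$score
    }
  }
  d <- max(score) + 1 - score
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "single")
  live <- profiles                       # cluster index -> profile
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(idx) if (idx < 0L) live[[-idx]] else merged[[idx]]
    A <- pick(tree$merge[k, 1L])
    B <- pick(tree$merge[k, 2L])
    r <- .align_profiles_cpp(A, B, params$submat,
                             params$gap_open, params$gap_extend)
    merged[[k]] <- merge_profiles(A, B, r$moves)
  }
  final <- merged[[n - 1L]]
  final <- final[match(ids, rownames(final)), , drop = FALSE]
  protein_alignment(ids, decode_profile(final, alphabet),
                    records$desc %||% rep("", n))
}

#' Run an external aligner on a barcoded FASTA file
#'
#' Adapter for re-aligning barcoded sequences with any standard alignment
#' tool (e.g. Clustal Omega, MAFFT). The command template must contain the
#' placeholders `{input}` and `{output}`; the command is run as a
#' subprocess and its output validated: every input record id must be
#' present and gap-stripped residues must be unchanged.
#'
#' @param input_path Path to the (unaligned) FASTA to align.
#' @param command_template Shell command with `{input}` and `{output}`
#'   placeholders, e.g. `"mafft --auto {input} > {output}"`.
#' @param output_path Where the aligned FASTA is written.
#' @return `output_path`, invisibly.
#' @export
external_aligner_adapter <- function(input_path, command_template,
                                     output_path = tempfile(fileext = ".fasta")) {
  if (!grepl("{input}", command_template, fixed = TRUE) ||
      !grepl("{output}", command_template, fixed = TRUE))
    cys_abort("parameter_error",
              "command template must contain {input} and {output}")
  cmd <- gsub("{input}", shQuote(input_path), command_template, fixed = TRUE)
  cmd <- gsub("{output}", shQuote(output_path), cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    cys_abort("aligner_failed_error",
              sprintf("external aligner exited with status %d: %s", status, cmd))
  input <- read_sequences(input_path)
  output <- tryCatch(read_alignment(output_path),
                     cysanchor_error = function(e) cys_abort(
                       "aligner_output_error",
                       sprintf("aligner output invalid: %s", conditionMessage(e))))
  lost <- setdiff(input$ids, output$ids)
  if (length(lost))
    cys_abort("lost_record_error", sprintf(
      "aligner output lost record(s): %s", paste(lost, collapse = ", ")))
  got <- strip_gaps(output$seqs)[match(input$ids, output$ids)]
  if (!identical(got, strip_gaps(input$seqs)))
    cys_abort("residue_mismatch_error",
              "aligner output altered residue content")
  invisible(output_path)
}
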