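#' Locate barcode spans in a re-aligned alignment
#'
#' For each record and each barcode its metadata expects, finds the unique
#' minimal column span whose gap-stripped content equals the barcode
#' sequence exactly. Aligners may break a barcode with internal gaps; the
#' span is therefore located on the gap-stripped sequence and mapped back to
#' alignment columns, with the number of internal gap columns reported.
#'
#' @param realigned A [protein_alignment()] of re-aligned barcoded records.
#' @param expected A list with one element per record (in record order),
#'   each a named character vector barcode_id -> barcode sequence giving the
#'   barcodes that record is expected to contain (may be empty).
#' @return A data frame of class `barcode_spans`: `record_id`, `barcode_id`,
#'   `start_column`, `end_column`, `internal_gap_count`.
#' @export
locate_barcodes <- function(realigned, expected) {
  stopifnot(inherits(realigned, "protein_alignment"))
  rows <- list()
  for (i in seq_along(realigned$ids)) {
    exp_i <- expected[[i]]
    if (!length(exp_i)) next
    seq_full <- realigned$seqs[i]
    chars <- strsplit(seq_full, "", fixed = TRUE)[[1L]]
    res_cols <- which(chars != "-")           # column of each residue
    stripped <- paste(chars[res_cols], collapse = "")
    for (b in seq_along(exp_i)) {
      bc <- exp_i[b]
      bid <- names(exp_i)[b]
      hits <- gregexpr(bc, stripped, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L)
        cys_abort("missing_barcode_error", sprintf(
          "barcode %s ('%s') not found in record '%s'",
          bid, bc, realigned$ids[i]))
      if (length(hits) > 1L)
        cys_abort("ambiguous_barcode_error", sprintf(
          "barcode %s found %d times in record '%s'",
          bid, length(hits), realigned$ids[i]))
      start_res <- hits[1L]
      end_res <- start_res + nchar(bc) - 1L
      start_col <- res_cols[start_res]
      end_col <- res_cols[end_res]
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = realigned$ids[i], barcode_id = bid,
        start_column = start_col, end_column = end_col,
        internal_gap_count = (end_col - start_col + 1L) - nchar(bc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(record_id = character(), barcode_id = character(),
               start_column = integer(), end_column = integer(),
               internal_gap_count = integer(), stringsAsFactors = FALSE)
  class(out) <- c("barcode_spans", "data.frame")
  out
}

#' Restore original columns in place of barcodes
#'
#' The closing half of the round trip. Metadata is decoded from the record
#' headers, each barcode span is located ([locate_barcodes()]), the span's
#' first column receives the stored original character and the remaining
#' span columns become gaps; when every record places a barcode on the same
#' columns (the designed behaviour of barcode anchoring) those residual
#' columns are entirely gaps and are removed, leaving the restored
#' characters in a single shared column. Span disagreement between records
#' is tolerated: the alignment is still produced, gap-padded, and the
#' report flags the barcode as misaligned naming the deviating records.
#'
#' All-gap columns are removed from the final alignment (cosmetic
#' normalisation) and metadata is stripped from the headers.
#'
#' @param realigned A [protein_alignment()] of re-aligned barcoded records
#'   with metadata headers (read with [read_alignment()]).
#' @param barcode_seqs Named character vector barcode_id -> barcode
#'   sequence. Defaults to the package default set extended by
#'   [reference_barcode_set()]; supply explicitly when custom barcodes were
#'   used.
#' @return A list of class `reconstruction`:
#'   \describe{
#'     \item{alignment}{the final [protein_alignment()]}
#'     \item{spans}{the located `barcode_spans`}
#'     \item{agreement}{data frame per barcode id: `aligned` (logical),
#'       `n_records`, `columns` (modal span), `deviating` (comma-separated
#'       record ids)}
#'     \item{warnings}{character vector of misalignment warnings}
#'   }
#' @export
reconstruct <- function(realigned, barcode_seqs = NULL) {
  stopifnot(inherits(realigned, "protein_alignment"))
  decoded <- lapply(realigned$ids, decode_metadata)
  metas <- lapply(decoded, `[[`, "meta")
  plain_ids <- vapply(decoded, `[[`, "", "record_id")
  if (all(vapply(metas, nrow, 1L) == 0L))
    cys_abort("no_metadata_error",
              "no round-trip metadata found in any record header")
  need_ids <- unique(unlist(lapply(metas, function(m) m$barcode_id)))
  if (is.null(barcode_seqs)) {
    pool <- default_barcodes(max(8L, length(need_ids) + 8L))
    barcode_seqs <- c(stats::setNames(pool$sequence, pool$id))
    ref <- reference_barcode_set()
    barcode_seqs <- c(barcode_seqs,
                      ref[setdiff(names(ref), names(barcode_seqs))])
  }
  unknown <- setdiff(need_ids, names(barcode_seqs))
  if (length(unknown))
    cys_abort("unknown_barcode_error", sprintf(
      "no sequence known for barcode id(s): %s; pass barcode_seqs",
      paste(unknown, collapse = ", ")))
  expected <- lapply(metas, function(m)
    stats::setNames(unname(barcode_seqs[m$barcode_id]), m$barcode_id))
  spans <- locate_barcodes(realigned, expected)

  m <- alignment_matrix(realigned)
  rownames(m) <- plain_ids
  # restore originals: first span column <- original char, rest <- gaps
  for (i in seq_along(plain_ids)) {
    meta <- metas[[i]]
    if (!nrow(meta)) next
    for (r in seq_len(nrow(meta))) {
      sp <- spans[spans$record_id == realigned$ids[i] &
                    spans$barcode_id == meta$barcode_id[r], ]
      cols <- sp$start_column:sp$end_column
      m[i, cols] <- "-"
      m[i, sp$start_column] <- meta$original[r]
    }
  }
  # per-barcode agreement check on span columns
  agreement <- list(); warnings <- character(0)
  for (bid in need_ids) {
    sp <- spans[spans$barcode_id == bid, , drop = FALSE]
    key <- paste(sp$start_column, sp$end_column)
    modal <- names(sort(table(key), decreasing = TRUE))[1L]
    deviating <- sp$record_id[key != modal]
    aligned <- length(deviating) == 0L
    if (!aligned) {
      warnings <- c(warnings, sprintf(
        "barcode %s spans disagree: record(s) %s deviate from the modal span",
        bid, paste(deviating, collapse = ", ")))
    }
    agreement[[bid]] <- data.frame(
      barcode_id = bid, aligned = aligned, n_records = nrow(sp),
      columns = modal,
      deviating = paste(deviating, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (w in warnings) cys_warn("span_disagreement_warning", w)
  keep <- colSums(m != "-") > 0L
  m <- m[, keep, drop = FALSE]
  structure(list(alignment = matrix_to_alignment(m),
                 spans = spans,
                 agreement = do.call(rbind, agreement),
                 warnings = warnings),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  ok <- sum(x$agreement$aligned)
  cat(sprintf("reconstruction: %d records, %d/%d barcode classes aligned\n",
              length(x$alignment$ids), ok, nrow(x$agreement)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Barcode, re-align and reconstruct in one call
#'
#' Convenience wrapper over [apply_barcodes()], [progressive_msa()] and
#' [reconstruct()]: the full anchored-alignment round trip with the built-in
#' aligner. For an external aligner, run the stages separately with
#' [write_barcoded()] and [external_aligner_adapter()].
#'
#' @inheritParams apply_barcodes
#' @param params An [align_params()] for the built-in aligner.
#' @return The [reconstruct()] result, with the `barcoded_set` attached as
#'   element `barcoded`.
#' @export
#' @examples
#' aln <- protein_alignment(c("a", "b", "c"),
#'                          c("KRCAA-DCE", "K-CAAMDCE", "KRC--MDCE"))
#' res <- barcode_pipeline(aln, columns = c(3, 8))
#' res$alignment
barcode_pipeline <- function(alignment, columns, barcodes = NULL,
                             params = align_params()) {
  bs <- apply_barcodes(alignment, columns, barcodes)
  realigned <- progressive_msa(list(ids = bs$headers, seqs = bs$seqs), params)
  seqs <- stats::setNames(bs$assignment$barcode_for_column,
                          bs$assignment$barcode_ids)
  out <- reconstruct(realigned, barcode_seqs = seqs)
  out$barcoded <- bs
  out
}
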