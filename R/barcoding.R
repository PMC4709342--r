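#' Replace homologous cysteine columns with peptide barcodes
#'
#' The forward half of the round trip. For every record, the character at
#' each requested alignment column is recorded (in the returned assignment
#' and in the FASTA header metadata) and replaced by a full barcode
#' sequence; all gap characters are then stripped so the inter-anchor loops
#' are free to re-align. Barcodes are drawn in rank order from `barcodes`
#' after collision checking against the gap-stripped input ([check_collisions()]),
#' so a barcode occurring naturally in the sequences is skipped for the next
#' suitable one.
#'
#' A record with a gap at a barcoded column still receives the barcode and
#' stores `-` as its original character: this keeps the scaffold anchored
#' and the round trip exact; such records are flagged in the report so the
#' user can exclude them. A warning (not an error) is raised when a replaced
#' character is neither `C` nor a gap, since anchoring is equally valid for
#' other structurally assignable residues such as catalytic ones.
#'
#' @param alignment A [protein_alignment()].
#' @param columns Integer vector of distinct 1-based alignment columns to
#'   barcode.
#' @param barcodes A `barcode_set` to draw from, in rank order; defaults to
#'   enough freshly generated default barcodes.
#' @return A list of class `barcoded_set`:
#'   \describe{
#'     \item{ids}{record ids}
#'     \item{headers}{ids with encoded round-trip metadata}
#'     \item{seqs}{unaligned barcoded sequences}
#'     \item{assignment}{a `barcode_assignment`: `columns`,
#'       `barcode_for_column` (named character: column -> barcode sequence),
#'       `barcode_ids` (column -> barcode id), `originals`
#'       (records x columns character matrix)}
#'     \item{collisions}{the [check_collisions()] report}
#'     \item{gap_records}{ids that had a gap in a barcoded column}
#'     \item{non_cysteine}{ids x column pairs where a non-cysteine residue
#'       was replaced}
#'   }
#' @export
#' @examples
#' aln <- protein_alignment(c("a", "b"), c("ARCDE", "AKC-E"))
#' bs <- apply_barcodes(aln, columns = 3)
#' bs$seqs
apply_barcodes <- function(alignment, columns, barcodes = NULL) {
  stopifnot(inherits(alignment, "protein_alignment"))
  columns <- as.integer(columns)
  if (length(columns) == 0L)
    cys_abort("parameter_error", "no columns to barcode")
  if (anyDuplicated(columns))
    cys_abort("duplicate_column_error", sprintf(
      "duplicate barcode column: %d", columns[duplicated(columns)][1L]))
  if (any(columns < 1L) || any(columns > alignment$ncol))
    cys_abort("column_range_error", sprintf(
      "column %d out of range 1..%d (columns are 1-based)",
      columns[columns < 1L | columns > alignment$ncol][1L], alignment$ncol))
  columns <- sort(columns)
  if (is.null(barcodes))
    barcodes <- default_barcodes(length(columns) + 8L)
  if (nrow(barcodes) < length(columns))
    cys_abort("insufficient_barcodes_error", sprintf(
      "%d columns requested but only %d barcodes supplied",
      length(columns), nrow(barcodes)))
  requested <- barcodes[seq_along(columns), , drop = FALSE]
  collisions <- check_collisions(requested, alignment$seqs, pool = barcodes)

  m <- alignment_matrix(alignment)
  originals <- m[, columns, drop = FALSE]
  colnames(originals) <- as.character(columns)
  non_cys <- which(matrix(!(originals %in% c("C", "-")), nrow(originals)),
                   arr.ind = TRUE)
  if (nrow(non_cys))
    cys_warn("non_cysteine_warning", sprintf(
      "%d barcoded position(s) hold a residue other than 'C' (e.g. '%s' at %s column %s)",
      nrow(non_cys), originals[non_cys[1L, , drop = FALSE]],
      rownames(m)[non_cys[1L, 1L]], colnames(originals)[non_cys[1L, 2L]]))
  gap_records <- rownames(m)[apply(originals == "-", 1L, any)]

  bc_seq <- collisions$used_sequence
  bc_id <- collisions$used
  names(bc_seq) <- names(bc_id) <- as.character(columns)

  headers <- character(length(alignment$ids))
  out_seqs <- character(length(alignment$ids))
  for (i in seq_along(alignment$ids)) {
    chars <- m[i, ]
    piece <- ifelse(chars == "-", "", chars)
    piece[columns] <- bc_seq
    out_seqs[i] <- paste(piece, collapse = "")
    meta <- barcode_metadata(columns, bc_id, originals[i, ])
    headers[i] <- encode_metadata(alignment$ids[i], meta)
  }
  structure(list(
    ids = alignment$ids,
    headers = headers,
    seqs = out_seqs,
    assignment = structure(list(columns = columns,
                                barcode_for_column = bc_seq,
                                barcode_ids = bc_id,
                                originals = originals),
                           class = "barcode_assignment"),
    collisions = collisions,
    gap_records = gap_records,
    non_cysteine = if (nrow(non_cys)) data.frame(
      record_id = rownames(m)[non_cys[, 1L]],
      column = columns[non_cys[, 2L]],
      residue = originals[non_cys],
      stringsAsFactors = FALSE) else NULL),
    class = "barcoded_set")
}

#' @export
print.barcoded_set <- function(x, ...) {
  cat(sprintf("barcoded_set: %d records, %d barcoded column(s) [%s]\n",
              length(x$ids), length(x$assignment$columns),
              paste(x$assignment$columns, collapse = ", ")))
  subs <- x$collisions[x$collisions$reason != "ok", , drop = FALSE]
  if (nrow(subs))
    cat(sprintf("  collisions: %s\n",
                paste(sprintf("%s -> %s", subs$requested, subs$used),
                      collapse = ", ")))
  if (length(x$gap_records))
    cat(sprintf("  gap at barcoded column: %s\n",
                paste(x$gap_records, collapse = ", ")))
  invisible(x)
}

#' Write barcoded sequences to FASTA
#'
#' Writes the unaligned barcoded records with their round-trip metadata
#' headers, ready for re-alignment by any standard aligner.
#'
#' @param x A `barcoded_set` from [apply_barcodes()] or
#'   [barcode_subgroup_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_barcoded <- function(x, path) {
  write_sequences(list(ids = x$headers, seqs = x$seqs), path)
}

#' Barcode and pool several sub-group alignments
#'
#' Cysteine-rich superfamilies are usually split into structure-anchored
#' sub-groups, each with its own alignment. To merge them, non-homologous
#' cysteines must be distinguished: each homology class label is assigned
#' one barcode, the same label receiving the same barcode in every
#' sub-group, so that joint re-alignment pins truly homologous cysteines
#' together and keeps non-homologous ones apart.
#'
#' @param subgroups A list; each element a list with `alignment` (a
#'   [protein_alignment()]), `columns` (integer vector), and `labels`
#'   (character vector, one homology-class label per column).
#' @param barcodes A `barcode_set` pool; defaults to enough default
#'   barcodes for all distinct labels.
#' @param label_barcodes Optional named character vector forcing
#'   label -> barcode sequence; inconsistent duplicate assignments raise a
#'   merge-conflict error.
#' @return A `barcoded_set` covering all records of all subgroups, with an
#'   extra element `label_map` (label -> barcode sequence).
#' @export
barcode_subgroup_set <- function(subgroups, barcodes = NULL,
                                 label_barcodes = NULL) {
  if (!length(subgroups))
    cys_abort("empty_input_error", "no subgroups supplied")
  all_labels <- character(0)
  for (sg in subgroups) {
    if (length(sg$columns) != length(sg$labels))
      cys_abort("input_mismatch_error",
                "each barcoded column needs exactly one class label")
    all_labels <- c(all_labels, as.character(sg$labels))
  }
  labels <- unique(all_labels)
  if (!is.null(label_barcodes)) {
    dup <- names(label_barcodes)[duplicated(names(label_barcodes))]
    for (dl in unique(dup)) {
      vals <- unique(label_barcodes[names(label_barcodes) == dl])
      if (length(vals) > 1L)
        cys_abort("merge_conflict_error", sprintf(
          "class '%s' assigned conflicting barcodes: %s",
          dl, paste(vals, collapse = " vs ")))
    }
    label_barcodes <- label_barcodes[!duplicated(names(label_barcodes))]
  }
  if (is.null(barcodes))
    barcodes <- default_barcodes(length(labels) + 8L)
  all_seqs <- unlist(lapply(subgroups, function(sg) sg$alignment$seqs))
  pool_report <- check_collisions(barcodes[seq_along(labels), , drop = FALSE],
                                  all_seqs, pool = barcodes)
  label_map <- pool_report$used_sequence
  label_ids <- pool_report$used
  names(label_map) <- names(label_ids) <- labels
  if (!is.null(label_barcodes)) {
    known <- intersect(names(label_barcodes), labels)
    label_map[known] <- label_barcodes[known]
    label_ids[known] <- paste0("custom.", seq_along(known))
  }

  pieces <- lapply(subgroups, function(sg) {
    cols <- as.integer(sg$columns)
    ord <- order(cols)
    cols <- cols[ord]; labs <- as.character(sg$labels)[ord]
    set <- data.frame(id = unname(label_ids[labs]),
                      sequence = unname(label_map[labs]),
                      stringsAsFactors = FALSE)
    class(set) <- c("barcode_set", "data.frame")
    apply_barcodes(sg$alignment, cols, barcodes = set)
  })
  ids <- unlist(lapply(pieces, `[[`, "ids"))
  if (anyDuplicated(ids))
    cys_abort("duplicate_id_error", sprintf(
      "record id '%s' appears in more than one subgroup",
      ids[duplicated(ids)][1L]))
  structure(list(
    ids = ids,
    headers = unlist(lapply(pieces, `[[`, "headers")),
    seqs = unlist(lapply(pieces, `[[`, "seqs")),
    assignment = lapply(pieces, `[[`, "assignment"),
    collisions = pool_report,
    gap_records = unlist(lapply(pieces, `[[`, "gap_records")),
    non_cysteine = do.call(rbind, lapply(pieces, `[[`, "non_cysteine")),
    label_map = label_map),
    class = "barcoded_set")
}
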