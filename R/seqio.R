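#' Construct a protein alignment
#'
#' The container every pipeline stage exchanges: a set of equal-length,
#' gapped, upper-case sequences with unique identifiers.
#'
#' @param ids Character vector of unique, non-empty identifiers (no
#'   whitespace).
#' @param seqs Character vector of gapped sequences, all the same length,
#'   using the residue letters `A`-`Z` and the gap character `-` (`.` is
#'   normalised to `-`, lower case is raised).
#' @param desc Optional character vector of free-text descriptions.
#' @return An object of class `protein_alignment`: a list with elements
#'   `ids`, `seqs`, `desc` and `ncol` (the column count).
#' @export
#' @examples
#' aln <- protein_alignment(c("a", "b"), c("AC-D", "AKCD"))
#' aln$ncol
protein_alignment <- function(ids, seqs, desc = rep("", length(ids))) {
  recs <- validate_records(ids, seqs, desc)
  widths <- nchar(recs$seqs)
  if (length(recs$ids) < 2L)
    cys_abort("empty_input_error", "an alignment needs at least 2 sequences")
  if (length(unique(widths)) != 1L) {
    bad <- recs$ids[widths != widths[1L]][1L]
    cys_abort("alignment_shape_error", sprintf(
      "sequences have unequal lengths: '%s' has %d columns, expected %d",
      bad, nchar(recs$seqs[recs$ids == bad][1L]), widths[1L]))
  }
  structure(list(ids = recs$ids, seqs = recs$seqs, desc = recs$desc,
                 ncol = widths[1L]),
            class = "protein_alignment")
}

# shared validation for aligned and unaligned sequence sets
validate_records <- function(ids, seqs, desc) {
  ids <- as.character(ids); seqs <- as.character(seqs)
  desc <- as.character(desc)
  if (length(ids) == 0L)
    cys_abort("empty_input_error", "no sequences supplied")
  if (length(ids) != length(seqs))
    cys_abort("input_mismatch_error", "ids and seqs differ in length")
  if (any(!nzchar(ids)) || any(grepl("[[:space:]]", ids)))
    cys_abort("invalid_id_error", "ids must be non-empty and whitespace-free")
  if (anyDuplicated(ids)) {
    cys_abort("duplicate_id_error",
              sprintf("duplicate sequence id: '%s'", ids[duplicated(ids)][1L]))
  }
  seqs <- chartr(".", "-", toupper(seqs))
  if (any(!nzchar(seqs)))
    cys_abort("empty_input_error", "empty sequence encountered")
  bad <- grepl("[^A-Z-]", seqs)
  if (any(bad)) {
    cys_abort("invalid_residue_error", sprintf(
      "sequence '%s' contains characters outside A-Z and '-'", ids[bad][1L]))
  }
  list(ids = ids, seqs = seqs, desc = desc)
}

#' @export
print.protein_alignment <- function(x, n = 6L, ...) {
  cat(sprintf("protein_alignment: %d sequences x %d columns\n",
              length(x$ids), x$ncol))
  show <- seq_len(min(n, length(x$ids)))
  w <- max(nchar(x$ids[show]))
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-*s %s\n", w, x$ids[i], s))
  }
  if (length(x$ids) > n) cat(sprintf("  ... %d more\n", length(x$ids) - n))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. Sequences are
#' upper-cased, `.` gaps are normalised to `-`, and all records must have the
#' same length. The first whitespace-delimited token of each header is the
#' id; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_alignment()].
#' @seealso [write_alignment()], [read_sequences()]
#' @export
read_alignment <- function(path) {
  recs <- read_sequences(path)
  protein_alignment(recs$ids, recs$seqs, recs$desc)
}

#' Read sequences from FASTA without requiring equal lengths
#'
#' Used for unaligned inputs such as barcoded sequences awaiting
#' re-alignment. Returns a plain record set (ids, seqs, desc) with the same
#' residue normalisation as [read_alignment()].
#'
#' @inheritParams read_alignment
#' @return A list with elements `ids`, `seqs`, `desc`.
#' @export
read_sequences <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) cys_abort(
                    "fasta_parse_error",
                    sprintf("could not parse FASTA '%s': %s",
                            path, conditionMessage(e))))
  if (length(set) == 0L)
    cys_abort("empty_input_error", sprintf("no sequences in '%s'", path))
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  validate_records(ids, as.character(set), desc)
}

#' Write an alignment (or record set) to FASTA
#'
#' Writes sequences wrapped at 60 characters. Headers are `id` or
#' `id description` when a description is present.
#'
#' @param x A [protein_alignment()] or a list with `ids`, `seqs` and
#'   optionally `desc`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  write_sequences(x, path)
}

#' @rdname write_alignment
#' @export
write_sequences <- function(x, path) {
  desc <- x$desc %||% rep("", length(x$ids))
  headers <- ifelse(nzchar(desc), paste(x$ids, desc), x$ids)
  set <- Biostrings::BStringSet(x$seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# ---- round-trip metadata codec -------------------------------------------
# Grammar (normative for this package):
#   header   := id | id "|CB:" entries
#   entries  := entry (";" entry)*
#   entry    := column "," barcode_id "," original
# column is a 1-based alignment column, barcode_id a token free of
# [,;|] and whitespace, original a single residue letter or '-'.

#' Construct barcode round-trip metadata
#'
#' The per-record ledger of which alignment column received which barcode and
#' what character it replaced; serialised into the FASTA header so the
#' original residues survive external re-alignment.
#'
#' @param column Integer vector of 1-based alignment columns, strictly
#'   increasing.
#' @param barcode_id Character vector of barcode identifiers (unique within
#'   the record, no `,`, `;`, `|` or whitespace).
#' @param original Character vector of single characters (`A`-`Z` or `-`),
#'   the residues the barcodes replaced.
#' @return A data frame of class `barcode_metadata`.
#' @export
#' @examples
#' barcode_metadata(c(3, 9), c("bc.001", "bc.002"), c("C", "-"))
barcode_metadata <- function(column = integer(), barcode_id = character(),
                             original = character()) {
  column <- as.integer(column)
  barcode_id <- as.character(barcode_id)
  original <- as.character(original)
  n <- length(column)
  if (length(barcode_id) != n || length(original) != n)
    cys_abort("invalid_metadata_error", "metadata fields differ in length")
  if (n > 0L) {
    if (any(is.na(column)) || any(column < 1L))
      cys_abort("invalid_metadata_error", "columns must be positive integers")
    if (any(diff(column) <= 0L))
      cys_abort("invalid_metadata_error", "columns must be strictly increasing")
    if (anyDuplicated(barcode_id))
      cys_abort("invalid_metadata_error", "barcode ids must be unique")
    if (any(grepl("[,;|[:space:]]", barcode_id)) || any(!nzchar(barcode_id)))
      cys_abort("invalid_metadata_error",
                "barcode ids must be non-empty and free of ',', ';', '|'")
    if (any(!grepl("^[A-Z-]$", original)))
      cys_abort("invalid_metadata_error",
                "original characters must be a single residue letter or '-'")
  }
  structure(data.frame(column = column, barcode_id = barcode_id,
                       original = original, stringsAsFactors = FALSE),
            class = c("barcode_metadata", "data.frame"))
}

#' Encode round-trip metadata into a FASTA header
#'
#' @param record_id Sequence identifier (no whitespace or `|`).
#' @param meta A [barcode_metadata()] object (possibly empty).
#' @return The header string `id|CB:col,bc,orig;...`; just `id` when the
#'   metadata is empty.
#' @seealso [decode_metadata()]
#' @export
#' @examples
#' encode_metadata("seq1", barcode_metadata(3, "bc.001", "C"))
encode_metadata <- function(record_id, meta) {
  if (!inherits(meta, "barcode_metadata"))
    meta <- do.call(barcode_metadata, as.list(meta))
  if (grepl("[[:space:]|]", record_id) || !nzchar(record_id))
    cys_abort("invalid_id_error",
              "record_id must be non-empty, without whitespace or '|'")
  if (nrow(meta) == 0L) return(record_id)
  entries <- paste(meta$column, meta$barcode_id, meta$original, sep = ",")
  paste0(record_id, "|CB:", paste(entries, collapse = ";"))
}

#' Decode a FASTA header into id and round-trip metadata
#'
#' Exact inverse of [encode_metadata()]; a header without a `|CB:` block
#' yields empty metadata.
#'
#' @param header Header string.
#' @return A list with elements `record_id` and `meta` (a
#'   [barcode_metadata()]).
#' @export
#' @examples
#' decode_metadata("seq1|CB:3,bc.001,C")
decode_metadata <- function(header) {
  if (!is.character(header) || length(header) != 1L || !nzchar(header))
    cys_abort("metadata_parse_error", "header must be a single non-empty string")
  if (!grepl("|CB:", header, fixed = TRUE))
    return(list(record_id = header, meta = barcode_metadata()))
  at <- regexpr("|CB:", header, fixed = TRUE)
  record_id <- substr(header, 1L, at - 1L)
  body <- substr(header, at + 4L, nchar(header))
  if (!nzchar(body))
    cys_abort("metadata_parse_error",
              sprintf("empty metadata block after position %d", at))
  entries <- strsplit(body, ";", fixed = TRUE)[[1L]]
  parts <- strsplit(entries, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) {
    cys_abort("metadata_parse_error", sprintf(
      "malformed metadata entry %d ('%s'): expected column,barcode_id,original",
      bad[1L], entries[bad[1L]]))
  }
  column <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  if (any(is.na(column)))
    cys_abort("metadata_parse_error", "non-integer column in metadata")
  meta <- tryCatch(
    barcode_metadata(column,
                     vapply(parts, `[[`, "", 2L),
                     vapply(parts, `[[`, "", 3L)),
    cysanchor_error = function(e) cys_abort(
      "metadata_parse_error",
      sprintf("invalid metadata in '%s': %s", header, conditionMessage(e))))
  list(record_id = record_id, meta = meta)
}

# strip gaps from a character vector of sequences
strip_gaps <- function(seqs) gsub("-", "", seqs, fixed = TRUE)

# alignment as a character matrix (rows = records)
alignment_matrix <- function(aln) {
  m <- matrix("", length(aln$ids), aln$ncol)
  sp <- strsplit(aln$seqs, "", fixed = TRUE)
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  rownames(m) <- aln$ids
  m
}

matrix_to_alignment <- function(m, desc = NULL) {
  protein_alignment(rownames(m), apply(m, 1L, paste, collapse = ""),
                    desc %||% rep("", nrow(m)))
}
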