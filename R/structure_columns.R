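#' Suggest homologous cysteine columns from a structure-based alignment
#'
#' A structural aligner (e.g. the DALI webserver) returns a sequence
#' alignment based on backbone superposition; cysteines that land in the
#' same or a neighbouring column of that alignment (a shift of less than
#' ~3 angstroms along the structure) are counted as structurally
#' homologous. This function clusters cysteine positions greedily left to
#' right: a class seeds at the leftmost unassigned cysteine column and
#' absorbs, from every other record, its unassigned cysteine within
#' `neighbour_window` columns of the seed (the closest one; ties go left).
#' Classes are labelled `I`, `II`, ... in column order.
#'
#' The result is marked `"suggested"`: confirming which classes to barcode
#' is deliberately left to the user, the one manual decision in the
#' pipeline.
#'
#' @param structure_alignment A [protein_alignment()] (the backbone-based
#'   alignment produced externally).
#' @param neighbour_window Non-negative integer; `0` restricts classes to
#'   shared columns.
#' @param residue The anchored residue letter, `"C"` by default.
#' @return An object of class `homology_classes`: list with `classes` (a
#'   named list of data frames `record_id`, `column`) and `provenance`.
#' @export
#' @examples
#' aln <- protein_alignment(c("a", "b"), c("ACD-C", "AC-CD"))
#' suggest_homologous_cysteine_columns(aln)
suggest_homologous_cysteine_columns <- function(structure_alignment,
                                                neighbour_window = 1L,
                                                residue = "C") {
  stopifnot(inherits(structure_alignment, "protein_alignment"))
  neighbour_window <- as.integer(neighbour_window)
  if (is.na(neighbour_window) || neighbour_window < 0L)
    cys_abort("parameter_error", "neighbour_window must be >= 0")
  m <- alignment_matrix(structure_alignment)
  pos <- which(m == residue, arr.ind = TRUE)
  pos <- data.frame(record = rownames(m)[pos[, 1L]], row = pos[, 1L],
                    column = pos[, 2L], stringsAsFactors = FALSE)
  pos <- pos[order(pos$column, pos$row), , drop = FALSE]
  pos$assigned <- FALSE
  classes <- list()
  repeat {
    open <- which(!pos$assigned)
    if (!length(open)) break
    seed <- open[1L]
    seed_col <- pos$column[seed]
    members <- integer(0)
    for (r in unique(pos$row)) {
      cand <- which(!pos$assigned & pos$row == r &
                      abs(pos$column - seed_col) <= neighbour_window)
      if (!length(cand)) next
      # one column per record per class: nearest to seed, ties leftward
      cand <- cand[order(abs(pos$column[cand] - seed_col), pos$column[cand])]
      members <- c(members, cand[1L])
    }
    pos$assigned[members] <- TRUE
    classes[[length(classes) + 1L]] <-
      data.frame(record_id = pos$record[members],
                 column = pos$column[members],
                 stringsAsFactors = FALSE)
  }
  names(classes) <- as.character(utils::as.roman(seq_along(classes)))
  structure(list(classes = classes, provenance = "suggested",
                 residue = residue, neighbour_window = neighbour_window),
            class = "homology_classes")
}

#' @export
print.homology_classes <- function(x, ...) {
  cat(sprintf("homology_classes (%s): %d class(es)\n",
              x$provenance, length(x$classes)))
  for (lab in names(x$classes)) {
    cl <- x$classes[[lab]]
    cat(sprintf("  %-4s %d member(s), columns %s\n", lab, nrow(cl),
                paste(sort(unique(cl$column)), collapse = ",")))
  }
  invisible(x)
}

#' Assign a query sequence to its closest structural sub-group
#'
#' Sequences without a solved structure are routed to the sub-group of
#' their closest relative with known structure. This network-free stand-in
#' for a BLAST search scores the query against every representative with
#' the built-in global aligner ([pairwise_align()]) and returns the
#' best-scoring one, ties broken by input order. An external BLAST search
#' can replace this step; only the chosen representative matters
#' downstream.
#'
#' @param query A gap-free sequence.
#' @param representatives Named (or unnamed) character vector of gap-free
#'   representative sequences, one per sub-group.
#' @param params An [align_params()].
#' @return A list: `representative` (name or index), `sequence`, `score`,
#'   and `scores` (all representatives).
#' @export
assign_to_subgroup <- function(query, representatives,
                               params = align_params()) {
  if (!length(representatives))
    cys_abort("parameter_error", "at least one representative is required")
  nm <- names(representatives) %||% as.character(seq_along(representatives))
  scores <- vapply(representatives, function(r)
    pairwise_align(strip_gaps(query), strip_gaps(r), params)$score,
    numeric(1), USE.NAMES = FALSE)
  best <- which.max(scores)   # first maximum: tie-break by input order
  list(representative = nm[best],
       sequence = unname(representatives[best]),
       score = scores[best],
       scores = stats::setNames(scores, nm))
}
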