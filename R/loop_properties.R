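#' Split aligned records into inter-anchor loops
#'
#' Cuts each record of a final alignment at its anchor (cysteine) columns.
#' Anchors are excluded from the loops; gaps are stripped; `k` anchors yield
#' `k + 1` loops per record, loop 0 being the N-terminal tail and the last
#' the C-terminal tail.
#'
#' @param alignment A [protein_alignment()] in final (reconstructed)
#'   coordinates.
#' @param anchor_columns Integer vector of 1-based anchor columns.
#' @return A named list (one element per record) of character vectors of
#'   gap-free loop sequences, each of length `length(anchor_columns) + 1`.
#' @export
#' @examples
#' aln <- protein_alignment(c("a", "b"), c("ACDCE", "KC-CE"))
#' split_loops(aln, c(2, 4))
split_loops <- function(alignment, anchor_columns) {
  stopifnot(inherits(alignment, "protein_alignment"))
  anchor_columns <- sort(as.integer(anchor_columns))
  if (any(anchor_columns < 1L) || any(anchor_columns > alignment$ncol))
    cys_abort("column_range_error", sprintf(
      "anchor column %d out of range 1..%d",
      anchor_columns[anchor_columns < 1L |
                       anchor_columns > alignment$ncol][1L], alignment$ncol))
  bounds <- c(0L, anchor_columns, alignment$ncol + 1L)
  out <- lapply(alignment$seqs, function(s) {
    vapply(seq_len(length(bounds) - 1L), function(k) {
      from <- bounds[k] + 1L; to <- bounds[k + 1L] - 1L
      if (from > to) return("")
      strip_gaps(substr(s, from, to))
    }, character(1))
  })
  names(out) <- alignment$ids
  out
}

#' Mean hydropathy of a peptide segment
#'
#' GRAVY-style mean of per-residue hydropathy values over the segment, by
#' default on the Kyte-Doolittle scale ([kyte_doolittle()]). Mean rather
#' than sum so that loops of different lengths are comparable; set
#' `aggregate = "sum"` for a total.
#'
#' @param x Gap-free residue string (may be empty).
#' @param scale Named numeric vector of per-residue values.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Numeric value; `NA` for an empty segment.
#' @export
#' @examples
#' hydropathy("III") # 4.5
#' hydropathy("R")   # -4.5
hydropathy <- function(x, scale = kyte_doolittle(), aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!nzchar(x)) return(NA_real_)
  res <- strsplit(x, "", fixed = TRUE)[[1L]]
  missing <- setdiff(res, names(scale))
  if (length(missing))
    cys_abort("unknown_residue_error", sprintf(
      "residue(s) %s absent from the hydropathy scale",
      paste(sQuote(missing), collapse = ", ")))
  v <- scale[res]
  if (aggregate == "mean") mean(v) else sum(v)
}

#' Net charge of a peptide segment at neutral pH
#'
#' Simple integer convention: +1 per K or R, -1 per D or E, a configurable
#' histidine contribution (0 by default, reflecting His being mostly
#' deprotonated at pH 7), all other residues 0. Termini are ignored: loops
#' are internal fragments. Unknown residue letters contribute 0 and are
#' reported via a message.
#'
#' @param x Gap-free residue string (may be empty).
#' @param histidine_charge Charge contribution per H.
#' @return Signed numeric charge.
#' @export
#' @examples
#' net_charge("KRDE") # 0
#' net_charge("KK")   # 2
net_charge <- function(x, histidine_charge = 0) {
  if (!nzchar(x)) return(0)
  res <- strsplit(x, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(res, AA20)
  if (length(unknown))
    message(sprintf("net_charge: unknown residue(s) %s treated as neutral",
                    paste(sQuote(unique(unknown)), collapse = ", ")))
  sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")) +
    histidine_charge * sum(res == "H")
}

#' Per-loop biophysical profiles
#'
#' For each record of a final alignment, splits it at the anchor columns
#' and computes per-loop length (residues, gaps excluded), mean hydropathy
#' and net charge - the per-loop statistics used to compare highly diverse
#' family members whose sequences cannot be compared directly.
#'
#' @inheritParams split_loops
#' @param scale Hydropathy scale passed to [hydropathy()].
#' @param aggregate Hydropathy aggregation, `"mean"` or `"sum"`.
#' @param histidine_charge Passed to [net_charge()].
#' @return A data frame of class `loop_profiles` with columns `record_id`,
#'   `loop_index` (0-based; 0 = N-terminal tail), `length`, `hydropathy`
#'   (`NA` for empty loops), `net_charge`.
#' @export
loop_profiles <- function(alignment, anchor_columns,
                          scale = kyte_doolittle(), aggregate = "mean",
                          histidine_charge = 0) {
  loops <- split_loops(alignment, anchor_columns)
  rows <- lapply(names(loops), function(id) {
    ls <- loops[[id]]
    data.frame(
      record_id = id,
      loop_index = seq_along(ls) - 1L,
      length = nchar(ls),
      hydropathy = vapply(ls, hydropathy, numeric(1),
                          scale = scale, aggregate = aggregate,
                          USE.NAMES = FALSE),
      net_charge = vapply(ls, net_charge, numeric(1),
                          histidine_charge = histidine_charge,
                          USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loop_profiles", "data.frame")
  out
}

#' Write / read loop statistics CSV
#'
#' Plain-text output of [loop_profiles()]: header
#' `record_id,loop_index,length,hydropathy,net_charge`, one row per
#' (record, loop), record order then loop index, empty-loop hydropathy
#' serialised as `NA`. The conventional filename is `loop_statistics.csv`.
#'
#' @param profiles A `loop_profiles` data frame.
#' @param path Output path.
#' @return `path` invisibly (for `write_loop_csv`); a `loop_profiles` data
#'   frame (for `read_loop_csv`).
#' @export
write_loop_csv <- function(profiles, path) {
  if (!nrow(profiles))
    cys_abort("empty_input_error", "no loop profiles to write")
  ok <- tryCatch(suppressWarnings({
    write.csv(profiles, path, row.names = FALSE, quote = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) cys_abort("io_error", sprintf("cannot write '%s'", path))
  invisible(path)
}

#' @rdname write_loop_csv
#' @export
read_loop_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "loop_index", "length", "hydropathy", "net_charge")
  if (!all(need %in% names(out)))
    cys_abort("io_error", sprintf(
      "'%s' is not a loop statistics CSV (missing %s)", path,
      paste(setdiff(need, names(out)), collapse = ", ")))
  out$record_id <- as.character(out$record_id)
  class(out) <- c("loop_profiles", "data.frame")
  out
}

#' @export
summary.loop_profiles <- function(object, ...) {
  by_loop <- split(object, object$loop_index)
  cat(sprintf("loop_profiles: %d records x %d loops\n",
              length(unique(object$record_id)), length(by_loop)))
  for (li in names(by_loop)) {
    d <- by_loop[[li]]
    cat(sprintf(
      "  loop %s: length %g-%g (median %g), hydropathy %s, charge %+.1f..%+.1f\n",
      li, min(d$length), max(d$length), stats::median(d$length),
      if (all(is.na(d$hydropathy))) "NA" else
        sprintf("%.2f..%.2f", min(d$hydropathy, na.rm = TRUE),
                max(d$hydropathy, na.rm = TRUE)),
      min(d$net_charge), max(d$net_charge)))
  }
  invisible(object)
}
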