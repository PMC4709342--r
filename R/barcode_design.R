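#' Composition Shannon entropy of a sequence
#'
#' Entropy in bits, `-sum(p * log2(p))`, over the residue composition of the
#' sequence. Used as the complexity filter for candidate barcodes: low-entropy
#' (repetitive) peptides align promiscuously and make poor anchors.
#'
#' @param x Character vector of gap-free sequences.
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' shannon_entropy("WWYHWYYHMM") # 1.971 bits
#' shannon_entropy("AAAAAAAAAA") # 0 bits
shannon_entropy <- function(x) {
  if (length(x) == 0L) return(numeric())
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      cys_abort("empty_input_error", "cannot compute entropy of empty sequence")
    if (grepl("-", s, fixed = TRUE))
      cys_abort("invalid_residue_error", "entropy is defined on gap-free sequences")
    p <- table(strsplit(s, "", fixed = TRUE)[[1L]]) / nchar(s)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which `a` and `b` differ. Substitution-only; see
#' [hamming_plus()] for the indel-aware variant used by the barcode design.
#'
#' @param a,b Gap-free strings of equal length.
#' @return Integer distance.
#' @export
#' @examples
#' hamming("WWYHWYYHMM", "WHWMMHYHYY") # 7
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    cys_abort("length_mismatch_error", sprintf(
      "hamming distance needs equal lengths (%d vs %d)", nchar(a), nchar(b)))
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Hamming-plus distance (unit-cost edit distance)
#'
#' The minimum number of substitutions plus insertions/deletions transforming
#' `a` into `b` - standard Levenshtein distance. This is the robustness
#' measure between barcodes: unlike plain Hamming distance it also guards
#' against barcodes aligning to one another with a frame shift. For
#' equal-length strings it is bounded above by [hamming()].
#'
#' @param a,b Gap-free strings; may differ in length, may be empty.
#' @return Integer edit distance.
#' @export
#' @examples
#' hamming_plus("AAAA", "AAA") # 1
hamming_plus <- function(a, b) {
  as.integer(adist(a, b)[1L, 1L])
}

#' Barcode design configuration
#'
#' Parameters of the barcode-set construction. The defaults encode the
#' design published with the method: 10-residue barcodes over the four
#' rarest amino acids (W, H, M, Y), composition entropy at least 1.8 bits,
#' pairwise Hamming-plus distance at least 4, and a default set size of 949.
#'
#' @param alphabet Character vector of at least 2 residue letters.
#' @param length Barcode length in residues.
#' @param entropy_min Minimum composition entropy in bits.
#' @param distance_min Minimum pairwise Hamming-plus distance.
#' @param count Number of barcodes requested.
#' @param background_freqs Named residue frequency vector for
#'   [match_probability()]; defaults to [aa_frequencies()].
#' @return A list of class `barcode_design_config`.
#' @export
barcode_design_config <- function(alphabet = c("W", "H", "M", "Y"),
                                  length = 10L,
                                  entropy_min = 1.8,
                                  distance_min = 4L,
                                  count = 949L,
                                  background_freqs = aa_frequencies()) {
  alphabet <- toupper(as.character(alphabet))
  if (length(alphabet) < 2L || anyDuplicated(alphabet) ||
      any(!grepl("^[A-Z]$", alphabet)))
    cys_abort("parameter_error",
              "alphabet must be >= 2 distinct single residue letters")
  length <- as.integer(length); count <- as.integer(count)
  distance_min <- as.integer(distance_min)
  if (length < 1L) cys_abort("parameter_error", "length must be >= 1")
  if (entropy_min < 0) cys_abort("parameter_error", "entropy_min must be >= 0")
  if (distance_min < 1L) cys_abort("parameter_error", "distance_min must be >= 1")
  if (count < 1L) cys_abort("parameter_error", "count must be >= 1")
  if (is.null(names(background_freqs)) || any(background_freqs < 0))
    cys_abort("parameter_error",
              "background_freqs must be a named non-negative vector")
  structure(list(alphabet = sort(alphabet), length = length,
                 entropy_min = entropy_min, distance_min = distance_min,
                 count = count, background_freqs = background_freqs),
            class = "barcode_design_config")
}

#' Chance-match probability of a barcode against random sequence
#'
#' Closed-form bound on the probability that the barcode occurs as an exact
#' substring anywhere in an alignment of random sequences drawn from
#' background residue frequencies. The per-window probability is the product
#' of the background frequencies of the barcode's residues; the total
#' multiplies it by the number of windows,
#' `n_sequences * (sequence_length - barcode_length + 1)` (floored at 0).
#'
#' @param barcode A gap-free barcode sequence.
#' @param config A [barcode_design_config()] supplying `background_freqs`.
#' @param n_sequences,sequence_length Alignment dimensions to bound against.
#' @return A list of class `match_risk` with `per_window_probability`,
#'   `total_probability`, `n_sequences`, `sequence_length`, `n_windows`.
#' @export
#' @examples
#' match_probability("MYYHHMYWYY", n_sequences = 1000, sequence_length = 1000)
match_probability <- function(barcode, config = barcode_design_config(),
                              n_sequences, sequence_length) {
  res <- strsplit(barcode, "", fixed = TRUE)[[1L]]
  freqs <- config$background_freqs
  missing <- setdiff(res, names(freqs))
  if (length(missing))
    cys_abort("unknown_residue_error", sprintf(
      "residue(s) %s absent from background frequency table",
      paste(sQuote(missing), collapse = ", ")))
  per_window <- prod(freqs[res])
  n_windows <- max(0L, as.integer(n_sequences) *
                     (as.integer(sequence_length) - length(res) + 1L))
  structure(list(per_window_probability = per_window,
                 total_probability = per_window * n_windows,
                 n_sequences = as.integer(n_sequences),
                 sequence_length = as.integer(sequence_length),
                 n_windows = n_windows),
            class = "match_risk")
}

#' @export
print.match_risk <- function(x, ...) {
  cat(sprintf(
    "match_risk: P(window) = %.3g, %d windows (%d seqs x length %d), P(match) = %.3g\n",
    x$per_window_probability, x$n_windows, x$n_sequences,
    x$sequence_length, x$total_probability))
  invisible(x)
}

#' Generate the default barcode set
#'
#' Deterministic construction of a set of mutually distinctive peptide
#' barcodes. Candidates (all `alphabet^length` strings) are enumerated in
#' lexicographic order; those below the entropy threshold are dropped; the
#' survivors are admitted greedily, a candidate joining the set only if its
#' Hamming-plus distance to every already-admitted barcode is at least
#' `distance_min`, until `count` barcodes are admitted or the pool is
#' exhausted (a warning, not an error). The admitted set is then ranked by
#' robustness - minimum Hamming-plus distance to the rest of the set,
#' descending - with ties broken by entropy (descending) then
#' lexicographically, and ids `bc.001`, `bc.002`, ... assigned in that final
#' order.
#'
#' @param config A [barcode_design_config()].
#' @return A data frame of class `barcode_set` with columns `id`, `sequence`,
#'   `entropy_bits`, `min_distance_to_set`.
#' @export
#' @examples
#' generate_default_barcodes(barcode_design_config(count = 8))
generate_default_barcodes <- function(config = barcode_design_config()) {
  stopifnot(inherits(config, "barcode_design_config"))
  key <- paste(c(config$alphabet, config$length, config$entropy_min,
                 config$distance_min, config$count), collapse = "/")
  hit <- .cys_cache$barcode_sets[[key]]
  if (!is.null(hit)) return(hit)
  k <- length(config$alphabet); len <- config$length
  n_cand <- k^len
  if (n_cand > 2^24)
    cys_abort("parameter_error", sprintf(
      "candidate space %s^%d is too large to enumerate", k, len))

  admitted_seq <- character(0)
  admitted_ent <- numeric(0)
  admitted_mat <- matrix(0L, 0L, len)
  chunk <- 65536L
  from <- 0
  while (from < n_cand && length(admitted_seq) < config$count) {
    idx <- from:min(from + chunk - 1, n_cand - 1)
    from <- from + chunk
    # digits of idx base k, most significant first = lexicographic order
    m <- matrix(0L, length(idx), len)
    rem <- idx
    for (j in len:1) { m[, j] <- as.integer(rem %% k) + 1L; rem <- rem %/% k }
    cnt <- vapply(seq_len(k), function(a) rowSums(m == a), numeric(nrow(m)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    p <- cnt / len
    ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
    keep <- which(ent >= config$entropy_min - 1e-9)
    for (i in keep) {
      cand_seq <- paste(config$alphabet[m[i, ]], collapse = "")
      if (length(admitted_seq)) {
        # cheap lower-bound screen: edit distance <= hamming at equal length
        hd <- colSums(admitted_mat_t != m[i, ])
        if (min(hd) < config$distance_min) next
        if (min(adist(cand_seq, admitted_seq)) < config$distance_min) next
      }
      admitted_seq <- c(admitted_seq, cand_seq)
      admitted_ent <- c(admitted_ent, ent[i])
      admitted_mat <- rbind(admitted_mat, m[i, ])
      admitted_mat_t <- t(admitted_mat)
      if (length(admitted_seq) >= config$count) break
    }
  }
  if (length(admitted_seq) < config$count)
    cys_warn("pool_exhausted_warning", sprintf(
      "candidate pool exhausted: %d of %d requested barcodes generated",
      length(admitted_seq), config$count))

  if (length(admitted_seq) > 1L) {
    d <- adist(admitted_seq)
    diag(d) <- NA_integer_
    min_d <- apply(d, 1L, min, na.rm = TRUE)
  } else {
    min_d <- rep(NA_integer_, length(admitted_seq))
  }
  ord <- order(-min_d, -admitted_ent, admitted_seq)
  out <- data.frame(
    id = sprintf("bc.%03d", seq_along(admitted_seq)),
    sequence = admitted_seq[ord],
    entropy_bits = admitted_ent[ord],
    min_distance_to_set = as.integer(min_d[ord]),
    stringsAsFactors = FALSE)
  class(out) <- c("barcode_set", "data.frame")
  if (is.null(.cys_cache$barcode_sets))
    .cys_cache$barcode_sets <- list()
  .cys_cache$barcode_sets[[key]] <- out
  out
}

#' First n default barcodes
#'
#' Convenience wrapper generating (and caching) a ranked default barcode set
#' of the requested size under the default design configuration.
#'
#' @param n Number of barcodes.
#' @return A `barcode_set` data frame with `n` rows (fewer, with a warning,
#'   if the candidate pool is exhausted).
#' @export
default_barcodes <- function(n) {
  generate_default_barcodes(barcode_design_config(count = n))
}

#' Check barcodes against input sequences and substitute on collision
#'
#' A barcode collides if its sequence occurs as an exact substring of any
#' (gap-stripped) input sequence; a colliding or already-used barcode is
#' skipped and the next barcode in rank order from `pool` is used instead.
#'
#' @param barcodes A `barcode_set` (the requested barcodes, in order).
#' @param sequences Character vector of input sequences (gaps are stripped
#'   before matching).
#' @param pool A `barcode_set` of substitutes, in rank order; defaults to
#'   `barcodes`.
#' @return A data frame of class `collision_report` with columns `requested`,
#'   `used`, `used_sequence`, `reason` (`"ok"` or `"collision"`).
#' @export
check_collisions <- function(barcodes, sequences, pool = barcodes) {
  stripped <- strip_gaps(sequences)
  collides <- function(bc) any(grepl(bc, stripped, fixed = TRUE))
  used <- character(0)
  rows <- vector("list", nrow(barcodes))
  for (i in seq_len(nrow(barcodes))) {
    req <- barcodes$sequence[i]
    req_id <- barcodes$id[i]
    if (!collides(req) && !(req %in% used)) {
      rows[[i]] <- data.frame(requested = req_id, used = req_id,
                              used_sequence = req, reason = "ok",
                              stringsAsFactors = FALSE)
      used <- c(used, req)
      next
    }
    # walk the pool for the next suitable barcode
    sub <- NULL
    for (j in seq_len(nrow(pool))) {
      cand <- pool$sequence[j]
      if (cand %in% used || collides(cand)) next
      sub <- j; break
    }
    if (is.null(sub))
      cys_abort("insufficient_barcodes_error", sprintf(
        "no collision-free substitute available for %s", req_id))
    rows[[i]] <- data.frame(requested = req_id, used = pool$id[sub],
                            used_sequence = pool$sequence[sub],
                            reason = "collision", stringsAsFactors = FALSE)
    used <- c(used, pool$sequence[sub])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("collision_report", "data.frame")
  out
}
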