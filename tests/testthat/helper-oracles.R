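# Independent oracles used to validate the package's implementations.
# Deliberately written in the most literal way possible, not shared with
# any code under test.

# unit-cost edit distance by textbook recursion (memoised)
oracle_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    if (!nzchar(a)) return(nchar(b))
    if (!nzchar(b)) return(nchar(a))
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ta <- substring(a, 2L); tb <- substring(b, 2L)
    cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
    v <- min(rec(ta, b) + 1L, rec(a, tb) + 1L, rec(ta, tb) + cost)
    memo[[key]] <- v
    v
  }
  rec(a, b)
}

# all strings over `alphabet` of length 0..max_len
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# score of one explicit alignment (move string over M/X/Y) under
# affine gaps: a gap run of length L costs open + (L-1)*extend.
# X = gap in b (consume a), Y = gap in a (consume b).
oracle_alignment_score <- function(a, b, moves, submat, open, extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  i <- 0L; j <- 0L; s <- 0; prev <- ""
  for (mv in moves) {
    if (mv == "M") {
      i <- i + 1L; j <- j + 1L
      s <- s + submat[ca[i], cb[j]]
    } else if (mv == "X") {
      i <- i + 1L
      s <- s - if (prev == "X") extend else open
    } else {
      j <- j + 1L
      s <- s - if (prev == "Y") extend else open
    }
    prev <- mv
  }
  s
}

# maximum global alignment score by exhaustive enumeration of all
# monotone paths (feasible for short sequences only)
oracle_best_score <- function(a, b, submat, open, extend) {
  na <- nchar(a); nb <- nchar(b)
  best <- -Inf
  walk <- function(i, j, moves) {
    if (i == na && j == nb) {
      s <- oracle_alignment_score(a, b, moves, submat, open, extend)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < na && j < nb) walk(i + 1L, j + 1L, c(moves, "M"))
    if (i < na) walk(i + 1L, j, c(moves, "X"))
    if (j < nb) walk(i, j + 1L, c(moves, "Y"))
  }
  walk(0L, 0L, character(0))
  best
}

# random gap-free peptide of given length (uses current RNG state)
random_peptide <- function(len, alphabet = c("A", "R", "N", "D", "C", "Q",
                                             "E", "G", "H", "I", "L", "K",
                                             "M", "F", "P", "S", "T", "W",
                                             "Y", "V")) {
  paste(alphabet[sample.int(length(alphabet), len, replace = TRUE)],
        collapse = "")
}

# fresh barcode-design cache so regeneration tests really regenerate
clear_barcode_cache <- function() {
  assign("barcode_sets", list(), envir = cysanchor:::.cys_cache)
}
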