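#' Average amino-acid background frequencies
#'
#' Relative frequencies of the 20 standard amino acids averaged over the
#' Swiss-Prot database (the composition table documented with the ExPASy
#' ProtParam tool). These are the default background used by
#' [match_probability()] to bound the chance that a barcode appears in
#' random protein sequence. The four rarest residues (W, C, H, M) motivate
#' the default barcode alphabet, with Y substituted for C because cysteine
#' is the residue being anchored.
#'
#' @return Named numeric vector of length 20 summing to ~1.
#' @export
#' @examples
#' aa_frequencies()[c("W", "H", "M", "Y")]
aa_frequencies <- function() {
  c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
    Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
    L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
    S = 0.0660, T = 0.0535, W = 0.0109, Y = 0.0292, V = 0.0687)
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values of Kyte & Doolittle (1982). Positive values
#' are hydrophobic (Ile 4.5), negative hydrophilic (Arg -4.5). Used as the
#' default scale by [hydropathy()] and [loop_profiles()]; a user-supplied
#' named vector with the same shape can replace it.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' kyte_doolittle()[c("I", "R", "G")]
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Reference set of eight anchoring barcodes
#'
#' The canonical first eight 10-residue peptide barcodes over the rare-residue
#' alphabet W/H/M/Y, used to pin homologous cysteine columns in place during
#' re-alignment. The set's published guarantees - every pair differs by at
#' least 7 substitutions, composition entropy is high, and chance identity to
#' random protein sequence is below 1e-10 for realistic alignment sizes - make
#' them safe anchors for any standard aligner. They double as a fixed test
#' surface for [shannon_entropy()], [hamming()] and [match_probability()].
#'
#' @return Named character vector (names `bc.001` ... `bc.008`).
#' @export
#' @examples
#' reference_barcode_set()
reference_barcode_set <- function() {
  c(bc.001 = "WWYHWYYHMM", bc.002 = "WHWMMHYHYY",
    bc.003 = "WWHHMWMMYW", bc.004 = "WHYYMMWMWM",
    bc.005 = "HWWMYHHMHW", bc.006 = "HMHYYWHHYM",
    bc.007 = "MMYMWMWHHW", bc.008 = "MYYHHMYWYY")
}

# the 20 standard residue letters
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
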