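#' IUPAC degenerate nucleotide codes
#'
#' Expansion sets for the 15 IUPAC nucleotide codes used in degenerate PCR
#' primers (e.g. R = A/G, Y = C/T, N = any base).
#'
#' @format A named list mapping each code to the character vector of plain
#'   bases it stands for.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Does an IUPAC code match a DNA base?
#'
#' @param primer_char Single IUPAC code (character).
#' @param base Single plain base, one of A/C/G/T.
#' @return `TRUE` iff `base` lies in the expansion set of `primer_char`;
#'   `N` matches every base.
#' @examples
#' iupac_matches("R", "A") # TRUE
#' iupac_matches("H", "G") # FALSE
#' @export
iupac_matches <- function(primer_char, base) {
  exp <- IUPAC_CODES[[primer_char]]
  if (is.null(exp)) {
    stop("invalid IUPAC code '", primer_char, "'")
  }
  if (!base %in% c("A", "C", "G", "T")) {
    stop("invalid DNA base '", base, "'")
  }
  base %in% exp
}

#' Count primer/window mismatches
#'
#' Hamming mismatch count of a degenerate primer against an equal-length DNA
#' window: a position counts as a mismatch when the window base is outside
#' the primer code's IUPAC expansion set.
#'
#' @param primer IUPAC string.
#' @param window Plain DNA string of the same length.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window)) {
    stop("primer (", nchar(primer), " nt) and window (", nchar(window),
         " nt) must have equal length")
  }
  pc <- strsplit(primer, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  sum(!mapply(iupac_matches, pc, wc))
}

#' Reverse complement preserving IUPAC codes
#'
#' @param x DNA/IUPAC string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Realize a degenerate sequence as concrete DNA
#'
#' Replaces each IUPAC code by one fixed base of its expansion set (the
#' lexicographically smallest), giving a deterministic concrete consensus.
#'
#' @param x IUPAC string.
#' @return Plain A/C/G/T string.
#' @export
iupac_realize <- function(x) {
  ch <- strsplit(x, "")[[1]]
  paste(vapply(ch, function(c) {
    exp <- IUPAC_CODES[[c]]
    if (is.null(exp)) stop("invalid IUPAC code '", c, "'")
    exp[[1]]
  }, character(1)), collapse = "")
}
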