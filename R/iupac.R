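# IUPAC nucleotide alphabet utilities shared across the package.
# Internal coordinates are 0-based half-open throughout.

#' IUPAC code expansion sets
#'
#' Mapping from each IUPAC nucleotide code to the set of unambiguous bases it
#' covers. `N` covers all four bases.
#'
#' @format Named list of character vectors.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 4-bit base encoding (A=1, C=2, G=4, T=8); ambiguity codes are bit unions.
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.iupac_bits_table <- local({
  v <- integer(128)
  for (code in names(IUPAC_SETS)) {
    v[utf8ToInt(code)] <- sum(.base_bits[IUPAC_SETS[[code]]])
  }
  v
})

.bits_to_code <- local({
  v <- character(16)
  for (code in names(IUPAC_SETS)) {
    v[sum(.base_bits[IUPAC_SETS[[code]]])] <- code
  }
  v
})

#' Convert a DNA string to its 4-bit IUPAC encoding
#'
#' @param seq Single DNA string (upper case, IUPAC alphabet).
#' @return Integer vector, one element per base; 0 for characters outside the
#'   IUPAC alphabet.
#' @keywords internal
seq_bits <- function(seq) {
  .iupac_bits_table[utf8ToInt(seq)]
}

# Strict template encoding: only unambiguous A/C/G/T carry bits; every
# ambiguity code (including N) gets 0, so an unknown template base can never
# confirm hybridization.
.template_bits_table <- local({
  v <- integer(128)
  for (b in names(.base_bits)) v[utf8ToInt(b)] <- .base_bits[[b]]
  v
})

template_bits <- function(seq) {
  .template_bits_table[utf8ToInt(seq)]
}

#' IUPAC code covering a set of bases
#'
#' @param bases Character vector of IUPAC codes to union.
#' @return Single IUPAC code covering the union of the inputs.
#' @keywords internal
iupac_union_code <- function(bases) {
  bits <- 0L
  for (b in bases) bits <- bitwOr(bits, .iupac_bits_table[utf8ToInt(b)])
  if (bits == 0L) stop("no valid bases to combine", call. = FALSE)
  .bits_to_code[bits]
}

#' Validate a DNA string against the IUPAC alphabet
#'
#' @param seq Character vector of sequences.
#' @param what Label used in error messages.
#' @return Invisibly `TRUE`; stops on the first offending character.
#' @keywords internal
check_iupac <- function(seq, what = "sequence") {
  ok <- grepl("^[ACGTRYSWKMBDHVN]*$", seq)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    ch <- regmatches(seq[bad], regexpr("[^ACGTRYSWKMBDHVN]", seq[bad]))
    stop(sprintf("%s %d contains non-IUPAC character '%s'", what, bad, ch),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalise raw sequence text to upper-case DNA
#'
#' Folds lower case to upper case and RNA `U` to `T`, then validates against
#' the IUPAC alphabet.
#'
#' @param seq Character vector.
#' @param what Label used in error messages.
#' @return Normalised character vector.
#' @keywords internal
normalise_dna <- function(seq, what = "sequence") {
  seq <- chartr("u", "t", seq)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  check_iupac(seq, what)
  seq
}

#' Reverse complement of IUPAC DNA strings
#'
#' @param seq Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTR")
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Mismatch count between a primer (IUPAC-expanded) and a literal template
# substring of the same length. Ambiguous template bases (incl. N) always
# count as mismatches.
primer_mismatches <- function(primer_bits, tmpl_chunk_bits) {
  sum(bitwAnd(primer_bits, tmpl_chunk_bits) == 0L)
}
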