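# IUPAC nucleotide alphabet helpers shared by the pcr and fixtures modules.

#' @keywords internal
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_EXPANSION)

#' Expand an IUPAC code to its set of concrete bases
#'
#' @param code single IUPAC nucleotide letter.
#' @return character vector of the A/C/G/T bases the code stands for.
#' @keywords internal
iupac_expand <- function(code) {
  out <- IUPAC_EXPANSION[[toupper(code)]]
  if (is.null(out)) stop("not an IUPAC nucleotide code: '", code, "'")
  out
}

#' Validate an IUPAC nucleotide string
#'
#' @param seq character scalar.
#' @param what label used in the error message.
#' @return the uppercased sequence, invisibly usable downstream.
#' @keywords internal
validate_iupac <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% IUPAC_LETTERS)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 what, chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  up
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' IUPAC-aware: ambiguity codes are complemented onto their mirrored code
#' (A<->T, C<->G, R<->Y, K<->M, S<->S, W<->W, B<->V, D<->H, N<->N), then the
#' string is reversed. Used both to synthesize the template-orientation form
#' of the reverse primer before alignment and to scan the minus strand of a
#' source sequence.
#'
#' @param seq IUPAC nucleotide string (case-insensitive; returned uppercase).
#' @return the reverse complement, uppercase.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("CCGYCAATTYMTTTRAGTTT")
#' @export
reverse_complement <- function(seq) {
  up <- validate_iupac(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(up)))
}

#' Turn an IUPAC pattern into a plain regular expression
#'
#' Each ambiguity code becomes a character class over its expansion set;
#' concrete bases are kept as-is. Used by the fixture generator to screen
#' random flanks and inserts for spurious primer sites.
#'
#' @keywords internal
iupac_regex <- function(pattern) {
  chars <- strsplit(validate_iupac(pattern, "pattern"), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    ex <- iupac_expand(ch)
    if (length(ex) == 1L) ex else paste0("[", paste(ex, collapse = ""), "]")
  }, character(1L)), collapse = "")
}
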