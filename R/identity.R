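#' Global pairwise percent identity of two nucleotide sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap penalties,
#' scoring match +1, mismatch -1, gap open -2, gap extend -0.5 by default.
#' Identity is the number of identical alignment columns divided by the
#' total number of alignment columns (gap columns count against identity),
#' expressed as a percent.  The function is symmetric in its arguments and
#' returns 100 exactly when the sequences are identical.
#'
#' @param seq_a,seq_b nucleotide sequences (character or
#'   [Biostrings::DNAString]); must be non-empty.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @param digits decimals in the reported percent (default 1).
#' @return percent identity in `[0, 100]`, rounded to `digits`.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 0.5, digits = 1) {
  a <- Biostrings::DNAString(as.character(seq_a))
  b <- Biostrings::DNAString(as.character(seq_b))
  if (length(a) == 0L || length(b) == 0L)
    stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  round(100 * Biostrings::nmatch(aln) / cols, digits)
}
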