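# Global pairwise alignment with fixed, simple scoring. The deduplication
# and monomer-complex matching thresholds (70% / 80%) are coarse, so a
# plain match/mismatch scheme is sufficient; the scoring is configurable.

align_scoring <- function(match = 1, mismatch = 0, gap_open = 10, gap_extend = 0.5) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

global_align <- function(seq_a, seq_b, scoring = align_scoring()) {
  alphabet <- unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]]))
  m <- matrix(scoring$mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- scoring$match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seq_a), Biostrings::BString(seq_b),
    type = "global", substitutionMatrix = m,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Global sequence identity between two sequences
#'
#' Identity is the number of identical aligned positions divided by the full
#' alignment length (gap columns included in the denominator), under a global
#' alignment with match +1, mismatch 0, gap open -10, gap extend -0.5.
#' Symmetric in its arguments.
#'
#' @param seq_a,seq_b non-empty one-letter sequences.
#' @param scoring alignment scoring produced by the internal scheme; exposed
#'   for sensitivity checks.
#' @return identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIK")
#' @export
pairwise_identity <- function(seq_a, seq_b, scoring = align_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    abort("pairwise_identity requires two non-empty sequences")
  }
  aln <- global_align(seq_a, seq_b, scoring)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

# Residue-index map between two sequences: positions aligned with identical
# letters, as (index in a, index in b) pairs over ungapped positions.
align_residue_map <- function(seq_a, seq_b, scoring = align_scoring()) {
  aln <- global_align(seq_a, seq_b, scoring)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-" & ca == cb
  tibble::tibble(pos_a = ia[keep], pos_b = ib[keep])
}
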