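#' Pairwise DNA alignment with affine gap penalties
#'
#' Aligns vectors of query and subject sequences element-wise (either side may
#' be length one and is recycled). Three modes are offered: `"local"`
#' (Smith-Waterman, used for read recruitment and novelty filtering),
#' `"global"` (Needleman-Wunsch, used for OTU clustering identity) and
#' `"overlap"` (end-gap-free global, used for contig-vs-truth comparison in
#' the style of vsearch's global aligner).
#'
#' Identity is always `matches / alignment columns * 100`, with gap columns
#' counting as non-matches; `N` never matches. Coordinates returned are
#' 0-based half-open on the input sequences.
#'
#' @param query,subject Character vectors of DNA sequences (`A`,`C`,`G`,`T`,`N`).
#' @param mode One of `"local"`, `"global"`, `"overlap"`.
#' @param scoring Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend`. `match` and `mismatch` are per-column scores
#'   (mismatch negative); a gap of length L costs `gap_open + L * gap_extend`.
#' @param keep_strings If `TRUE`, also return the gapped aligned strings
#'   (`qaln`, `saln`).
#' @return A tibble with one row per alignment: `score`, `identity` (percent),
#'   `matches`, `columns`, `mismatches`, `gapopens`, `qstart`, `qend`,
#'   `sstart`, `send` and optionally `qaln`, `saln`.
#' @examples
#' align_seqs("ACGTACGT", "ACGTACGT", mode = "global")$identity
#' @export
align_seqs <- function(query, subject, mode = c("local", "global", "overlap"),
                       scoring = default_scoring(), keep_strings = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.character(query), is.character(subject))
  res <- cpp_align_batch(query, subject, mode = mode,
                         match = scoring$match, mismatch = scoring$mismatch,
                         gap_open = scoring$gap_open,
                         gap_extend = scoring$gap_extend,
                         keep_strings = keep_strings)
  tibble::as_tibble(res)
}

#' Default alignment scoring scheme
#'
#' Match +2, mismatch -3, gap open 5, gap extend 2 (penalties positive),
#' i.e. a blastn-like scheme.
#' @return Named list of scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L)
}

#' Percent identity between two sequences
#'
#' Convenience wrapper around [align_seqs()] returning just the identity.
#'
#' @inheritParams align_seqs
#' @param a,b Single DNA sequences.
#' @return Percent identity (0-100), `NA` if no alignment exists.
#' @export
pair_identity <- function(a, b, mode = "global", scoring = default_scoring()) {
  align_seqs(a, b, mode = mode, scoring = scoring)$identity
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
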