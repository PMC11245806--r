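# Exact k-mer prefilter used before pairwise alignment.
#
# The prefilter is lossless at the thresholds it is used with: a local
# alignment of d mismatching columns over a query of length l leaves an exact
# shared run of at least (l - d) / (d + 1) bases (pigeonhole), so any
# candidate passing the identity threshold shares at least one exact k-mer
# with the target for suitable k.

extract_kmers <- function(seqs, k) {
  lens <- nchar(seqs)
  nk <- pmax(0L, lens - k + 1L)
  if (sum(nk) == 0) {
    return(data.table::data.table(kmer = character(0), idx = integer(0)))
  }
  idx <- rep(seq_along(seqs), nk)
  startpos <- sequence(nk)
  data.table::data.table(kmer = substring(seqs[idx], startpos,
                                          startpos + k - 1L),
                         idx = idx)
}

#' Candidate query/target pairs sharing an exact k-mer
#'
#' Returns the pairs (query index, target index) for which the query (on
#' either strand if `both_strands`) shares at least one exact k-mer with the
#' target. Used to skip hopeless alignments during read recruitment,
#' clustering and novelty filtering.
#'
#' @param queries,targets Character vectors of DNA sequences.
#' @param k K-mer length.
#' @param both_strands Also match the reverse complement of queries.
#' @return Tibble with columns `query` and `target` (integer indices),
#'   each pair once.
#' @export
kmer_candidates <- function(queries, targets, k = 15L, both_strands = TRUE) {
  tk <- extract_kmers(targets, k)
  data.table::setkey(tk, kmer)
  qseqs <- queries
  qidx <- seq_along(queries)
  if (both_strands) {
    qseqs <- c(queries, revcomp(queries))
    qidx <- c(qidx, seq_along(queries))
  }
  qk <- extract_kmers(qseqs, k)
  qk[, idx := qidx[idx]]
  qk <- unique(qk)
  hits <- tk[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(query = integer(0), target = integer(0)))
  }
  out <- unique(hits[, .(query = i.idx, target = idx)])
  data.table::setorder(out, query, target)
  tibble::as_tibble(out)
}

# largest lossless prefilter k for a given identity threshold (fraction) and
# sequence lengths; returns NA when no useful k exists
lossless_k <- function(threshold, len_a, len_b, cap = 32L) {
  d <- floor((len_a + len_b) * (1 - threshold))
  run <- floor((min(len_a, len_b) - d) / (d + 1))
  k <- min(cap, run)
  if (k < 12) return(NA_integer_)
  as.integer(k)
}
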