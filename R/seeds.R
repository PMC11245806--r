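#' Greedy centroid OTU clustering
#'
#' Clusters amplicon reads at a fixed identity radius (default 99%, a radius
#' wide enough to capture 16S copy variants within one genome). Exact
#' duplicates are first dereplicated; unique sequences are sorted by total
#' count (descending), ties broken lexicographically by sequence, and scanned
#' greedily: each sequence joins the first existing centroid (in founding
#' order) whose global pairwise identity is at least the threshold, otherwise
#' it founds a new centroid. Identity is matches / alignment columns over a
#' global alignment, gaps counting as mismatches.
#'
#' @param amplicons Tibble with columns `sequence` and `sample_id` (one row
#'   per read; a `count` column, if present, is used as read multiplicity).
#' @param identity Identity radius as a fraction in (0.5, 1].
#' @param scoring Alignment scoring, see [default_scoring()].
#' @return List with `seeds` (tibble: `otu_id`, `sequence`, `total_count`),
#'   `otu_table` (wide tibble: `otu_id` + per-sample counts) and `membership`
#'   (tibble: `sequence`, `otu_id`); OTU ids `OTU_0001`... in founding order.
#' @export
cluster_otus <- function(amplicons, identity = 0.99,
                         scoring = default_scoring()) {
  stopifnot(identity > 0.5, identity <= 1)
  if (nrow(amplicons) == 0) stop("no amplicon sequences", call. = FALSE)
  if (!"count" %in% names(amplicons)) amplicons$count <- 1L
  derep <- amplicons |>
    dplyr::group_by(.data$sequence, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  totals <- derep |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$sequence)

  seqs <- totals$sequence
  lens <- nchar(seqs)
  centroid_of <- integer(length(seqs))  # index into centroid list
  centroids <- integer(0)               # indices into seqs, founding order

  for (i in seq_along(seqs)) {
    cand <- centroids
    # lossless length-ratio bound: identity <= min(len)/max(len)
    if (length(cand) > 0) {
      ratio <- pmin(lens[i], lens[cand]) / pmax(lens[i], lens[cand])
      cand <- cand[ratio >= identity]
    }
    assigned <- 0L
    if (length(cand) > 0) {
      aln <- align_seqs(rep(seqs[i], length(cand)), seqs[cand],
                        mode = "global", scoring = scoring)
      ok <- which(aln$identity >= identity * 100)
      if (length(ok) > 0) assigned <- match(cand[ok[1]], centroids)
    }
    if (assigned == 0L) {
      centroids <- c(centroids, i)
      assigned <- length(centroids)
    }
    centroid_of[i] <- assigned
  }

  otu_ids <- sprintf("OTU_%04d", seq_along(centroids))
  membership <- tibble::tibble(sequence = seqs,
                               otu_id = otu_ids[centroid_of])
  counts_long <- derep |>
    dplyr::left_join(membership, by = "sequence") |>
    dplyr::group_by(.data$otu_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  otu_table <- counts_long |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L) |>
    dplyr::arrange(.data$otu_id)
  seeds <- tibble::tibble(
    otu_id = otu_ids,
    sequence = seqs[centroids],
    total_count = vapply(seq_along(centroids), function(ci) {
      sum(totals$total[centroid_of == ci])
    }, numeric(1)))
  list(seeds = seeds, otu_table = otu_table, membership = membership)
}

#' Per-sample relative abundances from an OTU table
#'
#' @param otu_table Wide tibble (`otu_id` + per-sample counts).
#' @return Long tibble: `otu_id`, `sample_id`, `count`, `rel_abundance`
#'   (count / sample total).
#' @export
otu_rel_abundance <- function(otu_table) {
  long <- tidyr::pivot_longer(otu_table, -"otu_id",
                              names_to = "sample_id", values_to = "count")
  long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abundance = .data$count / max(sum(.data$count), 1L)) |>
    dplyr::ungroup()
}

#' Partition seeds into novel and known against a reference set
#'
#' A seed is "known" if some local alignment against any reference record
#' covers at least `min_coverage` of the seed at an identity strictly above
#' the threshold (the novelty filter applied against a reference 16S
#' database). An empty reference leaves every seed novel.
#'
#' @param seeds Seed tibble (columns `otu_id`, `sequence`).
#' @param reference Sequence tibble (e.g. from [read_fasta()]); may have 0
#'   rows.
#' @param identity Identity threshold as a fraction.
#' @param min_coverage Minimum fraction of the seed that must be aligned.
#' @param scoring Alignment scoring.
#' @return List with `novel` and `known` seed tibbles; `known` gains
#'   `matched_ref` (best matching reference id).
#' @export
filter_known <- function(seeds, reference, identity = 0.99,
                         min_coverage = 0.95, scoring = default_scoring()) {
  if (nrow(seeds) == 0 || is.null(reference) || nrow(reference) == 0) {
    return(list(novel = seeds, known = seeds[0, , drop = FALSE]))
  }
  k <- if (identity >= 0.97) {
    lossless_k(identity, min(nchar(seeds$sequence)) * min_coverage,
               min(nchar(seeds$sequence)) * min_coverage)
  } else NA_integer_
  cand <- if (!is.na(k)) {
    kmer_candidates(seeds$sequence, reference$sequence, k = k)
  } else {
    tidyr::expand_grid(query = seq_len(nrow(seeds)),
                       target = seq_len(nrow(reference)))
  }
  matched_ref <- rep(NA_character_, nrow(seeds))
  best_ident <- rep(-Inf, nrow(seeds))
  if (nrow(cand) > 0) {
    aln <- align_seqs(seeds$sequence[cand$query],
                      reference$sequence[cand$target],
                      mode = "local", scoring = scoring)
    alnrc <- align_seqs(revcomp(seeds$sequence[cand$query]),
                        reference$sequence[cand$target],
                        mode = "local", scoring = scoring)
    use_rc <- alnrc$score > aln$score
    aln[use_rc, ] <- alnrc[use_rc, ]
    cover <- (aln$qend - aln$qstart) / nchar(seeds$sequence[cand$query])
    hit <- cover >= min_coverage & aln$identity > identity * 100
    for (j in which(hit)) {
      q <- cand$query[j]
      if (aln$identity[j] > best_ident[q]) {
        best_ident[q] <- aln$identity[j]
        matched_ref[q] <- reference$id[cand$target[j]]
      }
    }
  }
  known_idx <- which(!is.na(matched_ref))
  known <- seeds[known_idx, , drop = FALSE]
  if (nrow(known) > 0) known$matched_ref <- matched_ref[known_idx]
  list(novel = seeds[setdiff(seq_len(nrow(seeds)), known_idx), , drop = FALSE],
       known = known)
}

#' Select the samples for metagenome sequencing
#'
#' Ranks OTUs by their maximum per-sample relative abundance (descending,
#' ties by OTU id) and walks the ranked list, adding each OTU's
#' argmax-abundance sample (ties by sample id) to an ordered set until it
#' holds `n` samples. Walking continues past the top `n` OTUs when several of
#' them peak in the same sample, ensuring exactly `n` samples are selected.
#'
#' @param otu_table Wide OTU count tibble.
#' @param n Number of samples to select (1 to number of samples).
#' @return Character vector of sample ids, in selection order.
#' @export
select_samples <- function(otu_table, n) {
  samples <- setdiff(names(otu_table), "otu_id")
  if (n > length(samples)) {
    stop("n (", n, ") exceeds the number of samples (", length(samples), ")",
         call. = FALSE)
  }
  stopifnot(n >= 1)
  rel <- otu_rel_abundance(otu_table)
  ranked <- rel |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(max_rel = max(.data$rel_abundance),
                     top_sample = min(.data$sample_id[
                       .data$rel_abundance == max(.data$rel_abundance)]),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$max_rel), .data$otu_id)
  selected <- character(0)
  for (i in seq_len(nrow(ranked))) {
    if (!(ranked$top_sample[i] %in% selected)) {
      selected <- c(selected, ranked$top_sample[i])
    }
    if (length(selected) == n) return(selected)
  }
  # fewer OTUs than requested samples: fill deterministically
  c(selected, sort(setdiff(samples, selected)))[seq_len(n)]
}

#' Rank and select the top seed sequences
#'
#' Restricts OTU counts to the selected samples, ranks seeds by maximum
#' per-sample relative abundance within those samples (ties by total count
#' descending, then id) and returns the top `K`. Seeds outside the length
#' bounds are dropped with a warning (guards against non-amplicon junk; V3-V4
#' centroids are ~400-450 nt).
#'
#' @param seeds Seed tibble (`otu_id`, `sequence`).
#' @param otu_table Wide OTU count tibble.
#' @param selected_samples Character vector of sample ids.
#' @param K Maximum number of seeds to return.
#' @param length_bounds Length-2 numeric, allowed seed length range.
#' @return Seed tibble ranked by abundance with `rank`, `max_rel_abundance`
#'   and `total_count` columns (at most `K` rows).
#' @export
select_seeds <- function(seeds, otu_table, selected_samples, K = 300,
                         length_bounds = c(150, 600)) {
  stopifnot(K >= 1)
  lens <- nchar(seeds$sequence)
  bad <- lens < length_bounds[1] | lens > length_bounds[2]
  if (any(bad)) {
    warning(sum(bad), " seed(s) outside length bounds [",
            length_bounds[1], ", ", length_bounds[2], "] excluded",
            call. = FALSE)
    seeds <- seeds[!bad, , drop = FALSE]
  }
  sub <- otu_table[, c("otu_id", intersect(selected_samples,
                                           names(otu_table))), drop = FALSE]
  rel <- otu_rel_abundance(sub)
  stats <- rel |>
    dplyr::group_by(.data$otu_id) |>
    dplyr::summarise(max_rel_abundance = max(.data$rel_abundance),
                     total_count = sum(.data$count), .groups = "drop")
  out <- seeds[, setdiff(names(seeds), c("max_rel_abundance", "total_count",
                                         "rank"))] |>
    dplyr::inner_join(stats, by = "otu_id") |>
    dplyr::arrange(dplyr::desc(.data$max_rel_abundance),
                   dplyr::desc(.data$total_count), .data$otu_id) |>
    utils::head(K)
  out$rank <- seq_len(nrow(out))
  out
}
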