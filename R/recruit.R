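#' Recruitment parameters
#'
#' Thresholds controlling the collection of shotgun read pairs for the seeds.
#' Defaults are the operating point established on simulated data: 98%
#' minimum local-alignment identity and up to three matched seeds per pair,
#' with abundance tie-breaking.
#'
#' @param min_identity Minimum percent identity of a local alignment
#'   (90-100).
#' @param max_matches Multiplicity cap m: a pair matching more than m
#'   distinct seeds is discarded (1-10).
#' @param min_aln_len Minimum alignment length in nt (guards against spurious
#'   short local hits).
#' @param end_tol Seed-terminus tolerance delta (nt) for the geometry rule.
#' @param read_cover_tol Read-coverage tolerance epsilon (nt) for the
#'   geometry rule.
#' @param prefilter_k Exact k-mer prefilter length; at the default identity
#'   (98%) and 150 nt reads any true hit shares a 15-mer with the seed
#'   (pigeonhole over at most 3 mismatches), so the prefilter loses nothing.
#'   Set `prefilter = FALSE` in [align_to_seeds()] for the exhaustive path.
#' @param scoring Alignment scoring, see [default_scoring()].
#' @return Named list of class `seedrecon_recruit_params`.
#' @export
recruit_params <- function(min_identity = 98, max_matches = 3,
                           min_aln_len = 50, end_tol = 5,
                           read_cover_tol = 5, prefilter_k = 15L,
                           scoring = default_scoring()) {
  p <- as.list(environment())
  stopifnot(p$min_identity >= 90, p$min_identity <= 100,
            p$max_matches >= 1, p$max_matches <= 10,
            p$end_tol >= 0, p$read_cover_tol >= 0, p$min_aln_len > 0)
  class(p) <- "seedrecon_recruit_params"
  p
}

#' Align read mates to seeds
#'
#' Computes, for every mate x seed combination, the best local alignment on
#' either strand, and reports it when identity and alignment-length
#' thresholds are met (at most one hit per mate-seed combination; among
#' equal-scoring alignments the leftmost on the seed is kept). An exact
#' k-mer prefilter skips mate-seed combinations sharing no `prefilter_k`-mer;
#' at the default thresholds this is lossless, and with `prefilter = FALSE`
#' the hit set is the exhaustive one.
#'
#' @param pairs Paired-read tibble ([read_fastq_pair()] layout).
#' @param seeds Seed tibble (`otu_id`, `sequence`).
#' @param params [recruit_params()].
#' @param prefilter Use the k-mer prefilter (default `TRUE`).
#' @return Hit tibble: `read_id`, `mate`, `seed_id`, `identity`, `aln_len`,
#'   `mismatch`, `gapopen`, `read_start`, `read_end` (0-based half-open on
#'   the forward-orientation read), `seed_start`, `seed_end`, `strand`,
#'   `score`, `read_len`, `seed_len`.
#' @export
align_to_seeds <- function(pairs, seeds, params = recruit_params(),
                           prefilter = TRUE) {
  if (nrow(seeds) == 0) stop("no seeds provided", call. = FALSE)
  empty <- tibble::tibble(
    read_id = character(0), mate = integer(0), seed_id = character(0),
    identity = numeric(0), aln_len = integer(0), mismatch = integer(0),
    gapopen = integer(0), read_start = integer(0), read_end = integer(0),
    seed_start = integer(0), seed_end = integer(0), strand = character(0),
    score = integer(0), read_len = integer(0), seed_len = integer(0))
  if (nrow(pairs) == 0) return(empty)
  mates <- tibble::tibble(
    read_id = rep(pairs$pair_id, 2),
    mate = rep(c(1L, 2L), each = nrow(pairs)),
    seq = c(pairs$seq1, pairs$seq2))
  if (prefilter) {
    cand <- kmer_candidates(mates$seq, seeds$sequence,
                            k = params$prefilter_k, both_strands = TRUE)
  } else {
    cand <- tidyr::expand_grid(query = seq_len(nrow(mates)),
                               target = seq_len(nrow(seeds)))
  }
  if (nrow(cand) == 0) return(empty)
  q <- mates$seq[cand$query]
  s <- seeds$sequence[cand$target]
  fwd <- align_seqs(q, s, mode = "local", scoring = params$scoring)
  rev <- align_seqs(revcomp(q), s, mode = "local", scoring = params$scoring)
  use_rev <- rev$score > fwd$score
  aln <- fwd
  aln[use_rev, ] <- rev[use_rev, ]
  strand <- ifelse(use_rev, "-", "+")
  read_len <- nchar(q)
  # convert minus-strand spans to forward-orientation read coordinates
  read_start <- ifelse(use_rev, read_len - aln$qend, aln$qstart)
  read_end <- ifelse(use_rev, read_len - aln$qstart, aln$qend)
  hits <- tibble::tibble(
    read_id = mates$read_id[cand$query],
    mate = mates$mate[cand$query],
    seed_id = seeds$otu_id[cand$target],
    identity = aln$identity,
    aln_len = aln$columns,
    mismatch = aln$mismatches,
    gapopen = aln$gapopens,
    read_start = as.integer(read_start),
    read_end = as.integer(read_end),
    seed_start = aln$sstart,
    seed_end = aln$send,
    strand = strand,
    score = aln$score,
    read_len = as.integer(read_len),
    seed_len = nchar(s))
  hits <- hits[!is.na(hits$identity) &
                 hits$identity >= params$min_identity &
                 hits$aln_len >= params$min_aln_len, , drop = FALSE]
  dplyr::arrange(hits, .data$read_id, .data$mate, .data$seed_id)
}

#' Alignment-geometry filter
#'
#' A hit passes if either (a) the alignment covers the whole read (up to
#' `read_cover_tol` nt slack), or (b) it terminates at a seed end (within
#' `end_tol` nt) with every unaligned read portion longer than
#' `read_cover_tol` hanging off that abutted terminus — i.e. the read would
#' extend beyond the seed, not into it. Internal partial alignments are
#' rejected; these are the reads that "partially match" the seed and would
#' seed mosaic assemblies.
#'
#' @param hits Hit tibble from [align_to_seeds()] (needs `read_len`,
#'   `seed_len` columns).
#' @param params [recruit_params()].
#' @return Logical vector, one element per hit row.
#' @export
geometry_pass <- function(hits, params = recruit_params()) {
  if (nrow(hits) == 0) return(logical(0))
  eps <- params$read_cover_tol
  delta <- params$end_tol
  # unaligned read portions in alignment orientation: `pre` sits against the
  # seed 5' end, `suf` against the seed 3' end
  pre <- ifelse(hits$strand == "+", hits$read_start,
                hits$read_len - hits$read_end)
  suf <- ifelse(hits$strand == "+", hits$read_len - hits$read_end,
                hits$read_start)
  (pre <= eps | hits$seed_start <= delta) &
    (suf <= eps | hits$seed_end >= hits$seed_len - delta)
}

#' Assign read pairs to seeds under the multiplicity cap
#'
#' For each pair, the matched set is the union of seeds hit (geometry-passing)
#' by either mate. Empty set: discarded (`no_hit`; only emitted when
#' `pair_ids` is supplied). More than `max_matches` seeds: discarded
#' (`too_many_seeds`). Otherwise the whole pair is assigned to the matched
#' seed with the highest relative abundance in this sample (ties broken by
#' lexicographically smallest seed id); seeds absent from the abundance table
#' count as abundance 0.
#'
#' @param hits Geometry-passing hit tibble.
#' @param sample_id Sample the reads belong to.
#' @param abundance Long abundance tibble ([otu_rel_abundance()] output) or a
#'   named numeric vector of per-seed relative abundances for this sample.
#' @param params [recruit_params()].
#' @param pair_ids Optional character vector of all pair ids in the sample;
#'   pairs without hits are then reported as `no_hit`.
#' @return Assignment tibble: `pair_id`, `sample_id`, `assigned_seed`
#'   (`NA` when discarded), `reason` (`assigned`, `no_hit`,
#'   `too_many_seeds`), `matched_seeds` (comma-joined), `n_matched`,
#'   `tie_break_used`.
#' @export
assign_pairs <- function(hits, sample_id, abundance,
                         params = recruit_params(), pair_ids = NULL) {
  ab <- seed_abundance_vector(abundance, sample_id)
  matched <- hits |>
    dplyr::distinct(.data$read_id, .data$seed_id) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(matched_seeds = paste(sort(.data$seed_id),
                                           collapse = ","),
                     n_matched = dplyr::n(),
                     assigned_seed = {
      sds <- sort(.data$seed_id)
      a <- unname(ab[sds]); a[is.na(a)] <- 0
      sds[which.max(a)]  # ties: first of the sorted ids
    }, .groups = "drop")
  out <- tibble::tibble(
    pair_id = matched$read_id,
    sample_id = sample_id,
    assigned_seed = ifelse(matched$n_matched > params$max_matches,
                           NA_character_, matched$assigned_seed),
    reason = ifelse(matched$n_matched > params$max_matches,
                    "too_many_seeds", "assigned"),
    matched_seeds = matched$matched_seeds,
    n_matched = matched$n_matched,
    tie_break_used = matched$n_matched > 1 &
      matched$n_matched <= params$max_matches)
  if (!is.null(pair_ids)) {
    missing <- setdiff(pair_ids, out$pair_id)
    if (length(missing) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        pair_id = missing, sample_id = sample_id,
        assigned_seed = NA_character_, reason = "no_hit",
        matched_seeds = "", n_matched = 0L, tie_break_used = FALSE))
    }
    out <- out[match(pair_ids, out$pair_id), , drop = FALSE]
  }
  out
}

# normalize the abundance argument to a named vector for one sample
seed_abundance_vector <- function(abundance, sample_id) {
  if (is.numeric(abundance) && !is.null(names(abundance))) return(abundance)
  stopifnot(is.data.frame(abundance))
  sub <- abundance[abundance$sample_id == sample_id, , drop = FALSE]
  if (nrow(sub) == 0 && nrow(abundance) > 0) {
    stop("sample '", sample_id, "' absent from abundance table",
         call. = FALSE)
  }
  stats::setNames(sub$rel_abundance, sub$otu_id)
}

#' Recruit one sample's read pairs to the seeds
#'
#' Convenience wrapper: alignment, geometry filtering and pair assignment in
#' one call.
#'
#' @inheritParams align_to_seeds
#' @param abundance Abundance table or named vector (see [assign_pairs()]).
#' @return List with `hits` (geometry-passing hits) and `assignments`.
#' @export
recruit_sample <- function(pairs, seeds, abundance,
                           params = recruit_params(), prefilter = TRUE) {
  sample_id <- if (nrow(pairs) > 0) pairs$sample_id[1] else ""
  hits <- align_to_seeds(pairs, seeds, params, prefilter = prefilter)
  hits <- hits[geometry_pass(hits, params), , drop = FALSE]
  assignments <- assign_pairs(hits, sample_id, abundance, params,
                              pair_ids = pairs$pair_id)
  list(hits = hits, assignments = assignments)
}

#' Sweep the minimum-identity threshold
#'
#' Runs recruitment at each threshold on identical inputs (alignment is
#' performed once at the loosest threshold, then filtered, so per-threshold
#' hit sets are nested by construction). When reads carry provenance tags and
#' a seed truth map is given, correct/incorrect assigned-pair counts are
#' reported as well.
#'
#' @inheritParams recruit_sample
#' @param thresholds Numeric vector of identity thresholds within \[90, 100\].
#' @param truth_map Optional [build_seed_truth()] tibble for
#'   correct/incorrect accounting.
#' @return Tibble of class `seedrecon_sweep`: one row per threshold with
#'   `n_hits`, `n_assigned`, and when truth is available `n_correct`,
#'   `n_incorrect`.
#' @export
sweep_identity <- function(pairs, seeds, abundance, thresholds,
                           params = recruit_params(), truth_map = NULL,
                           prefilter = TRUE) {
  if (length(thresholds) == 0) {
    return(structure(tibble::tibble(min_identity = numeric(0),
                                    n_hits = integer(0),
                                    n_assigned = integer(0)),
                     class = c("seedrecon_sweep", class(tibble::tibble()))))
  }
  stopifnot(all(thresholds >= 90), all(thresholds <= 100))
  base_params <- params
  base_params$min_identity <- min(thresholds)
  hits <- align_to_seeds(pairs, seeds, base_params, prefilter = prefilter)
  sample_id <- if (nrow(pairs) > 0) pairs$sample_id[1] else ""
  rows <- purrr::map_dfr(sort(thresholds), function(t) {
    h <- hits[hits$identity >= t, , drop = FALSE]
    h <- h[geometry_pass(h, params), , drop = FALSE]
    asg <- assign_pairs(h, sample_id, abundance, params)
    row <- tibble::tibble(min_identity = t, n_hits = nrow(h),
                          n_assigned = sum(asg$reason == "assigned"))
    if (!is.null(truth_map) && "genome" %in% names(pairs)) {
      sc <- score_recruitment(asg, truth_map, pairs)
      row$n_correct <- sum(sc$n_correct)
      row$n_incorrect <- sum(sc$n_incorrect)
    }
    row
  })
  structure(rows, class = c("seedrecon_sweep", class(rows)))
}

#' Sweep the multiplicity cap
#'
#' Re-assigns a fixed set of geometry-passing hits under each multiplicity
#' cap m. m = 1 is the strict uniqueness criterion; the assigned-pair count
#' is non-decreasing in m.
#'
#' @param hits Geometry-passing hit tibble (fixed across m values).
#' @param sample_id Sample the hits belong to.
#' @param abundance Abundance table or named vector.
#' @param m_values Integer vector of caps to evaluate.
#' @param params [recruit_params()].
#' @param truth_map,pairs Optional truth map and provenance-tagged pairs for
#'   correct/incorrect accounting.
#' @return Tibble of class `seedrecon_sweep`: one row per m with
#'   `n_assigned` (and `n_correct`/`n_incorrect` when truth is available).
#' @export
sweep_multiplicity <- function(hits, sample_id, abundance, m_values = 1:10,
                               params = recruit_params(), truth_map = NULL,
                               pairs = NULL) {
  rows <- purrr::map_dfr(sort(m_values), function(m) {
    p <- params; p$max_matches <- m
    asg <- assign_pairs(hits, sample_id, abundance, p)
    row <- tibble::tibble(max_matches = m,
                          n_assigned = sum(asg$reason == "assigned"))
    if (!is.null(truth_map) && !is.null(pairs)) {
      sc <- score_recruitment(asg, truth_map, pairs)
      row$n_correct <- sum(sc$n_correct)
      row$n_incorrect <- sum(sc$n_incorrect)
    }
    row
  })
  structure(rows, class = c("seedrecon_sweep", class(rows)))
}

#' Pool assigned pairs into per-seed bins
#'
#' Merges assignments across samples into one bin per seed; pair ids are made
#' unique by prefixing the sample id.
#'
#' @param assignments Assignment tibble(s) ([assign_pairs()] output, possibly
#'   row-bound over samples).
#' @param pairs Paired-read tibble covering all assigned pairs.
#' @return Nested tibble: `seed_id`, `n_pairs`, `pairs` (list column of
#'   paired-read tibbles with sample-prefixed pair ids).
#' @export
bin_pairs <- function(assignments, pairs) {
  asg <- assignments[assignments$reason == "assigned", , drop = FALSE]
  keyed <- dplyr::inner_join(
    asg[, c("pair_id", "sample_id", "assigned_seed")], pairs,
    by = c("pair_id", "sample_id"))
  if (nrow(keyed) < nrow(asg)) {
    stop("assignments reference pairs missing from `pairs`", call. = FALSE)
  }
  keyed$pair_id <- paste(keyed$sample_id, keyed$pair_id, sep = ":")
  if (anyDuplicated(paste(keyed$assigned_seed, keyed$pair_id))) {
    stop("colliding pair ids after sample prefixing", call. = FALSE)
  }
  keyed |>
    dplyr::rename(seed_id = "assigned_seed") |>
    tidyr::nest(pairs = -"seed_id") |>
    dplyr::mutate(n_pairs = vapply(.data$pairs, nrow, integer(1))) |>
    dplyr::select("seed_id", "n_pairs", "pairs") |>
    dplyr::arrange(.data$seed_id)
}

#' Write per-seed bins as FASTQ mate-file pairs
#'
#' @param bins Nested bin tibble from [bin_pairs()].
#' @param dir Output directory; files are `<seed_id>_R1.fastq` /
#'   `<seed_id>_R2.fastq`.
#' @return Tibble of written file paths, invisibly.
#' @export
write_bins <- function(bins, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map2_dfr(bins$seed_id, bins$pairs, function(sid, p) {
    f1 <- file.path(dir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(dir, paste0(sid, "_R2.fastq"))
    write_fastq_pair(p, f1, f2)
    tibble::tibble(seed_id = sid, r1 = f1, r2 = f2)
  })
  invisible(paths)
}
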