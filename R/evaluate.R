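#' Map seeds to their genome of origin via the truth 16S set
#'
#' A seed maps to a truth record when a local alignment covers at least
#' `min_coverage` of the seed at identity >= `identity`. Seeds mapping to two
#' genomes at equal best identity are ambiguous and excluded from scoring
#' (but reported); unmapped seeds are reported too.
#'
#' @param seeds Seed tibble (`otu_id`, `sequence`).
#' @param truth_16s Truth sequence tibble ([truth_tables()] `truth_16s`,
#'   needs `genome` column).
#' @param identity Identity threshold (percent).
#' @param min_coverage Minimum aligned fraction of the seed.
#' @param scoring Alignment scoring.
#' @return Tibble: `seed_id`, `genome`, `truth_id`, `identity`, `status`
#'   (`mapped`, `unmapped`, `ambiguous`); `genome` is `NA` unless mapped.
#' @export
build_seed_truth <- function(seeds, truth_16s, identity = 99,
                             min_coverage = 0.95,
                             scoring = default_scoring()) {
  purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    s <- seeds$sequence[i]
    fwd <- align_seqs(rep(s, nrow(truth_16s)), truth_16s$sequence,
                      mode = "local", scoring = scoring)
    rev <- align_seqs(rep(revcomp(s), nrow(truth_16s)), truth_16s$sequence,
                      mode = "local", scoring = scoring)
    use_rev <- rev$score > fwd$score
    aln <- fwd
    aln[use_rev, ] <- rev[use_rev, ]
    cover <- (aln$qend - aln$qstart) / nchar(s)
    ok <- which(aln$identity >= identity & cover >= min_coverage)
    if (length(ok) == 0) {
      return(tibble::tibble(seed_id = seeds$otu_id[i], genome = NA_character_,
                            truth_id = NA_character_, identity = NA_real_,
                            status = "unmapped"))
    }
    best <- max(aln$identity[ok])
    at_best <- ok[aln$identity[ok] == best]
    genomes <- unique(truth_16s$genome[at_best])
    if (length(genomes) > 1) {
      return(tibble::tibble(seed_id = seeds$otu_id[i], genome = NA_character_,
                            truth_id = NA_character_, identity = best,
                            status = "ambiguous"))
    }
    tibble::tibble(seed_id = seeds$otu_id[i], genome = genomes,
                   truth_id = truth_16s$id[at_best[1]], identity = best,
                   status = "mapped")
  })
}

#' Correct/incorrect recruitment accounting
#'
#' A pair is correct when its provenance genome equals the genome of the seed
#' it was assigned to (genome-level scoring: recruitment across 16S copies of
#' one genome counts as correct). Requires provenance-tagged reads; untagged
#' reads in scoring mode are an error. Seeds without a truth mapping are
#' excluded.
#'
#' @param assignments Assignment tibble ([assign_pairs()] output, possibly
#'   multi-sample).
#' @param truth_map [build_seed_truth()] tibble.
#' @param pairs Paired-read tibble carrying a `genome` column.
#' @return Tibble: `seed_id`, `sample_id`, `n_correct`, `n_incorrect`
#'   (`n_correct + n_incorrect` equals pairs assigned to that seed in that
#'   sample, for mapped seeds).
#' @export
score_recruitment <- function(assignments, truth_map, pairs) {
  asg <- assignments[assignments$reason == "assigned", , drop = FALSE]
  mapped <- truth_map[truth_map$status == "mapped", c("seed_id", "genome")]
  asg <- dplyr::inner_join(asg, mapped,
                           by = c(assigned_seed = "seed_id"))
  if (nrow(asg) == 0) {
    return(tibble::tibble(seed_id = character(0), sample_id = character(0),
                          n_correct = integer(0), n_incorrect = integer(0)))
  }
  prov <- pairs[, c("pair_id", "sample_id", "genome")]
  names(prov)[3] <- "read_genome"
  asg <- dplyr::inner_join(asg, prov, by = c("pair_id", "sample_id"))
  if (any(is.na(asg$read_genome))) {
    stop("untagged reads in scoring mode (no genome= provenance)",
         call. = FALSE)
  }
  asg |>
    dplyr::group_by(seed_id = .data$assigned_seed, .data$sample_id) |>
    dplyr::summarise(
      n_correct = sum(.data$read_genome == .data$genome),
      n_incorrect = sum(.data$read_genome != .data$genome),
      .groups = "drop")
}

#' Reconstruction success report
#'
#' Scores each reconstructed contig against the truth 16S set using
#' end-gap-free global alignment (the identity definition used for the
#' success criterion, distinct from recruitment's local identity): best
#' identity over truth records, coverage of that truth record, and a success
#' flag at >= 99% identity. Failed reconstructions (length 0) appear with
#' `success = FALSE`, giving the pairs-vs-length scatter its y = 0 points.
#'
#' @param results `seedrecon_assembly` tibble.
#' @param truth_16s Truth sequence tibble.
#' @param success_identity Identity threshold for success (percent).
#' @param scoring Alignment scoring.
#' @return Tibble: `seed_id`, `length`, `n_pairs`, `best_truth_id`,
#'   `identity`, `coverage` (percent of the truth record aligned), `success`.
#' @export
reconstruction_report <- function(results, truth_16s,
                                  success_identity = 99,
                                  scoring = default_scoring()) {
  purrr::map_dfr(seq_len(nrow(results)), function(i) {
    row <- tibble::tibble(
      seed_id = results$seed_id[i], length = results$length[i],
      n_pairs = results$n_pairs[i], best_truth_id = NA_character_,
      identity = NA_real_, coverage = NA_real_, success = FALSE)
    if (is.na(results$sequence[i]) || results$length[i] == 0) return(row)
    s <- results$sequence[i]
    fwd <- align_seqs(rep(s, nrow(truth_16s)), truth_16s$sequence,
                      mode = "overlap", scoring = scoring)
    rev <- align_seqs(rep(revcomp(s), nrow(truth_16s)), truth_16s$sequence,
                      mode = "overlap", scoring = scoring)
    use_rev <- rev$score > fwd$score
    aln <- fwd
    aln[use_rev, ] <- rev[use_rev, ]
    best <- which.max(aln$identity)
    row$best_truth_id <- truth_16s$id[best]
    row$identity <- aln$identity[best]
    row$coverage <- 100 * (aln$send[best] - aln$sstart[best]) /
      nchar(truth_16s$sequence[best])
    row$success <- row$identity >= success_identity
    row
  })
}

#' Long-format tables behind the evaluation figures
#'
#' Collects sweep outputs, recruitment scores and reconstruction reports into
#' plotting-ready long tibbles (threshold or multiplicity by
#' correct/incorrect counts; per-seed pairs-vs-length), optionally written as
#' TSVs.
#'
#' @param identity_sweeps Named list (by sample or condition) of
#'   [sweep_identity()] tibbles, or `NULL`.
#' @param multiplicity_sweeps Named list of [sweep_multiplicity()] tibbles,
#'   or `NULL`.
#' @param reconstruction [reconstruction_report()] tibble, or `NULL`.
#' @param dir Optional output directory for TSV files.
#' @return Named list of tibbles (`identity_sweep`, `multiplicity_sweep`,
#'   `pairs_vs_length`), omitting `NULL` inputs.
#' @export
figure_tables <- function(identity_sweeps = NULL, multiplicity_sweeps = NULL,
                          reconstruction = NULL, dir = NULL) {
  out <- list()
  bind_named <- function(lst) {
    dplyr::bind_rows(purrr::imap(lst, function(x, nm) {
      x <- tibble::as_tibble(x)
      x$condition <- nm
      x
    }))
  }
  if (!is.null(identity_sweeps)) {
    out$identity_sweep <- bind_named(identity_sweeps) |>
      tidyr::pivot_longer(dplyr::any_of(c("n_correct", "n_incorrect")),
                          names_to = "class", values_to = "n_pairs")
  }
  if (!is.null(multiplicity_sweeps)) {
    out$multiplicity_sweep <- bind_named(multiplicity_sweeps) |>
      tidyr::pivot_longer(dplyr::any_of(c("n_correct", "n_incorrect")),
                          names_to = "class", values_to = "n_pairs")
  }
  if (!is.null(reconstruction)) {
    out$pairs_vs_length <- reconstruction[, c("seed_id", "n_pairs", "length",
                                              "identity", "success")]
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
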