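#' Assembly parameters
#'
#' Controls the built-in seeded consensus extender. The seed acts as a
#' trusted backbone: it is never altered, only extended outward while
#' per-position read support is unanimous enough.
#'
#' @param k Anchor k-mer size used to shortlist reads against the contig
#'   terminus (15 <= k < read length).
#' @param min_cov Minimum number of overhanging reads supporting a position
#'   for extension to proceed.
#' @param max_len Contig length cap (the 16S gene plus margin).
#' @param min_report_len Minimum contig length of interest; 800 nt covers
#'   more than half of a full-length 16S gene.
#' @param branch_ratio Required ratio of dominant to second base support at a
#'   position; extension halts on ambiguity rather than forking, preferring
#'   conservative truncation over mosaic risk.
#' @param min_identity Minimum percent identity for a read-to-contig
#'   placement.
#' @param min_anchor_len Minimum placement alignment length (nt).
#' @param scoring Alignment scoring, see [default_scoring()].
#' @return Named list of class `seedrecon_assembly_params`.
#' @export
assembly_params <- function(k = 31L, min_cov = 3L, max_len = 1700L,
                            min_report_len = 800L, branch_ratio = 3,
                            min_identity = 96, min_anchor_len = 40L,
                            scoring = default_scoring()) {
  p <- as.list(environment())
  stopifnot(p$k >= 15, p$min_cov >= 1, p$branch_ratio >= 1,
            p$min_anchor_len >= p$k %/% 2)
  class(p) <- "seedrecon_assembly_params"
  p
}

# Overhangs of mates across the right end of `contig`. Returns character
# vector of overhanging strings (possibly empty).
right_overhangs <- function(contig, mates, params) {
  w_len <- min(nchar(contig), 400L)
  window <- substr(contig, nchar(contig) - w_len + 1L, nchar(contig))
  cand <- kmer_candidates(mates, window, k = params$k, both_strands = TRUE)
  if (nrow(cand) == 0) return(character(0))
  q <- mates[cand$query]
  fwd <- align_seqs(q, window, mode = "local", scoring = params$scoring)
  rev <- align_seqs(revcomp(q), window, mode = "local",
                    scoring = params$scoring)
  use_rev <- rev$score > fwd$score
  aln <- fwd
  aln[use_rev, ] <- rev[use_rev, ]
  oriented <- ifelse(use_rev, revcomp(q), q)
  ok <- !is.na(aln$identity) & aln$identity >= params$min_identity &
    aln$columns >= params$min_anchor_len & aln$send >= w_len - 3L
  over <- character(0)
  used <- integer(0)
  for (j in which(ok)) {
    # skip read bases matching contig positions still ahead of the window end
    skip <- w_len - aln$send[j]
    start <- aln$qend[j] + skip + 1L
    if (start <= nchar(oriented[j])) {
      over <- c(over, substr(oriented[j], start, nchar(oriented[j])))
      used <- c(used, cand$query[j])
    } else {
      used <- c(used, cand$query[j])
    }
  }
  attr(over, "used") <- unique(used)
  over
}

# Majority-vote consensus over overhang strings; stops at the first position
# lacking min_cov support or a dominant/second ratio >= branch_ratio.
consensus_extension <- function(overhangs, params, max_add) {
  if (length(overhangs) == 0 || max_add <= 0) return("")
  maxlen <- min(max(nchar(overhangs)), max_add)
  out <- character(0)
  for (pos in seq_len(maxlen)) {
    bases <- substr(overhangs[nchar(overhangs) >= pos], pos, pos)
    bases <- bases[bases %in% c("A", "C", "G", "T")]
    if (length(bases) < params$min_cov) break
    tab <- sort(table(bases), decreasing = TRUE)
    top <- tab[1]
    second <- if (length(tab) > 1) tab[2] else 0
    if (second > 0 && top / second < params$branch_ratio) break
    # deterministic tie-break can't trigger here (ratio >= 1 requires top >
    # second under branch_ratio > 1), but order names for safety
    out <- c(out, names(tab)[1])
  }
  paste(out, collapse = "")
}

#' Seeded assembly of one read bin
#'
#' Greedy consensus extension with the seed as a trusted backbone: reads are
#' oriented onto the current contig terminus by exact k-mer anchoring plus
#' local alignment; the per-position majority base among overhanging reads
#' extends the contig while support is at least `min_cov` and the dominant
#' base outweighs the runner-up by `branch_ratio`; both ends are extended
#' alternately until no direction grows or `max_len` is reached. Paired
#' rescue is implicit: every mate of the bin is re-considered against each
#' new terminus.
#'
#' @param bin Paired-read tibble (one seed's bin; [bin_pairs()] `pairs`
#'   element).
#' @param seed One-row seed tibble (`otu_id`, `sequence`) or a list with
#'   those names.
#' @param params [assembly_params()].
#' @return One-row tibble: `seed_id`, `sequence` (`NA` on failure), `length`
#'   (0 on failure), `n_pairs`, `n_pairs_used`, `seed_start`, `seed_end`
#'   (seed span in the contig, 0-based half-open), `status` (`ok`/`failed`).
#' @export
assemble_seed <- function(bin, seed, params = assembly_params()) {
  seed_id <- if (!is.null(seed$otu_id)) seed$otu_id[[1]] else seed$id[[1]]
  seed_seq <- seed$sequence[[1]]
  stopifnot(nchar(seed_seq) >= params$k, params$max_len > nchar(seed_seq))
  fail <- tibble::tibble(
    seed_id = seed_id, sequence = NA_character_, length = 0L,
    n_pairs = if (is.null(bin)) 0L else nrow(bin),
    n_pairs_used = 0L, seed_start = NA_integer_, seed_end = NA_integer_,
    status = "failed")
  if (is.null(bin) || nrow(bin) == 0) return(fail)

  mates <- c(bin$seq1, bin$seq2)
  mate_pair <- rep(seq_len(nrow(bin)), 2)
  contig <- seed_seq
  left_added <- 0L
  extended_ever <- FALSE
  repeat {
    grew <- FALSE
    # right
    ov <- right_overhangs(contig, mates, params)
    ext <- consensus_extension(ov, params, params$max_len - nchar(contig))
    if (nchar(ext) > 0) {
      contig <- paste0(contig, ext)
      grew <- TRUE
    }
    # left: extend the reverse complement rightward
    if (nchar(contig) < params$max_len) {
      rc <- revcomp(contig)
      ov <- right_overhangs(rc, mates, params)
      ext <- consensus_extension(ov, params, params$max_len - nchar(contig))
      if (nchar(ext) > 0) {
        contig <- paste0(revcomp(ext), contig)
        left_added <- left_added + nchar(ext)
        grew <- TRUE
      }
    }
    if (grew) extended_ever <- TRUE
    if (!grew || nchar(contig) >= params$max_len) break
  }

  if (!extended_ever && nrow(bin) < params$min_cov) return(fail)

  # count pairs supporting the final contig
  cand <- kmer_candidates(mates, contig, k = params$k, both_strands = TRUE)
  used_pairs <- integer(0)
  if (nrow(cand) > 0) {
    q <- mates[cand$query]
    fwd <- align_seqs(q, contig, mode = "local", scoring = params$scoring)
    rev <- align_seqs(revcomp(q), contig, mode = "local",
                      scoring = params$scoring)
    sc <- pmax(fwd$score, rev$score)
    idn <- ifelse(rev$score > fwd$score, rev$identity, fwd$identity)
    cols <- ifelse(rev$score > fwd$score, rev$columns, fwd$columns)
    ok <- !is.na(idn) & idn >= params$min_identity &
      cols >= params$min_anchor_len
    used_pairs <- unique(mate_pair[cand$query[ok]])
  }
  tibble::tibble(
    seed_id = seed_id, sequence = contig, length = nchar(contig),
    n_pairs = nrow(bin), n_pairs_used = length(used_pairs),
    seed_start = left_added, seed_end = left_added + nchar(seed_seq),
    status = "ok")
}

#' Assemble every seed bin
#'
#' @param bins Nested bin tibble from [bin_pairs()].
#' @param seeds Seed tibble (`otu_id`, `sequence`); seeds without a bin are
#'   reported as failed with zero pairs.
#' @param params [assembly_params()].
#' @return Tibble of class `seedrecon_assembly`, one row per seed (see
#'   [assemble_seed()]).
#' @export
assemble_bins <- function(bins, seeds, params = assembly_params()) {
  rows <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    sid <- seeds$otu_id[i]
    j <- match(sid, bins$seed_id)
    bin <- if (is.na(j)) NULL else bins$pairs[[j]]
    assemble_seed(bin, seeds[i, ], params)
  })
  structure(rows, class = c("seedrecon_assembly", class(rows)))
}

#' Partition reconstructions by minimum reported length
#'
#' The boundary is inclusive: a contig of exactly `min_report_len` is
#' reported.
#'
#' @param results `seedrecon_assembly` tibble.
#' @param min_report_len Minimum length of interest (nt).
#' @return List with `reported` and `short` tibbles; `short` rows that were
#'   `ok` get status `below_min_len`. Partition sizes sum to the input size.
#' @export
length_filter <- function(results, min_report_len = 800) {
  keep <- results$length >= min_report_len
  short <- results[!keep, , drop = FALSE]
  short$status[short$status == "ok"] <- "below_min_len"
  list(reported = results[keep, , drop = FALSE], short = short)
}

#' Simplified two-parent chimera check
#'
#' A uchime-inspired single-crossover model: for each query, per-position
#' match profiles against every parent are computed from end-gap-free global
#' alignments; the best single-parent identity I1 is compared with the best
#' chimeric identity I2 over all ordered parent pairs and crossover points
#' (scanned at `step` nt). The query is flagged when I2 - I1 >=
#' `min_improve` percentage points and the two parents are mutually at most
#' (100 - `min_div`)% identical. This is deliberately simpler than a full
#' uchime implementation and is not claimed to replicate vsearch verdicts.
#'
#' @param contigs Sequence tibble to check (`id`, `sequence`). Records whose
#'   id appears in the pool are excluded from their own parent set.
#' @param parent_pool Sequence tibble of candidate parents (seed set or
#'   reported contigs). Pools with fewer than 2 usable parents yield `clean`.
#' @param min_div Minimum mutual parent divergence (percent).
#' @param min_improve Minimum identity improvement of the chimeric model
#'   (percentage points).
#' @param step Crossover scan step (nt).
#' @param scoring Alignment scoring.
#' @return Tibble: `id`, `chimera` (`clean`/`flagged`), `i1`, `i2`,
#'   `parent_a`, `parent_b` (best chimeric pair, `NA` when clean by
#'   definition).
#' @export
chimera_check <- function(contigs, parent_pool, min_div = 3,
                          min_improve = 2, step = 10,
                          scoring = default_scoring()) {
  # mutual identity of parents, computed once
  np <- nrow(parent_pool)
  pid <- matrix(NA_real_, np, np)
  if (np >= 2) {
    for (a in seq_len(np - 1)) {
      for (b in (a + 1):np) {
        idn <- pair_identity(parent_pool$sequence[a],
                             parent_pool$sequence[b],
                             mode = "global", scoring = scoring)
        pid[a, b] <- pid[b, a] <- idn
      }
    }
  }
  purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
    id <- contigs$id[i]
    seq <- contigs$sequence[i]
    L <- nchar(seq)
    keep <- which(parent_pool$id != id)
    base <- tibble::tibble(id = id, chimera = "clean", i1 = NA_real_,
                           i2 = NA_real_, parent_a = NA_character_,
                           parent_b = NA_character_)
    if (length(keep) < 2 || L < 2 * step) return(base)
    # per-contig-position match profile for each parent
    prof <- vapply(keep, function(pidx) {
      aln <- align_seqs(seq, parent_pool$sequence[pidx], mode = "overlap",
                        scoring = scoring, keep_strings = TRUE)
      v <- numeric(L)
      qa <- strsplit(aln$qaln, "")[[1]]
      sa <- strsplit(aln$saln, "")[[1]]
      qpos <- aln$qstart
      for (c in seq_along(qa)) {
        if (qa[c] != "-") {
          qpos <- qpos + 1L
          if (sa[c] == qa[c] && qa[c] != "N") v[qpos] <- 1
        }
      }
      v
    }, numeric(L))
    cums <- apply(prof, 2, cumsum)  # L x parents
    tots <- cums[L, ]
    i1 <- max(tots) / L * 100
    cuts <- seq(step, L - step, by = step)
    best <- c(i2 = -Inf, a = NA, b = NA)
    for (ai in seq_along(keep)) {
      for (bi in seq_along(keep)) {
        if (ai == bi) next
        div_ok <- pid[keep[ai], keep[bi]] <= 100 - min_div
        if (!div_ok) next
        i2v <- (cums[cuts, ai] + tots[bi] - cums[cuts, bi]) / L * 100
        m <- max(i2v)
        if (m > best["i2"]) best <- c(i2 = m, a = ai, b = bi)
      }
    }
    i2 <- unname(best["i2"])
    flagged <- is.finite(i2) && (i2 - i1 >= min_improve)
    tibble::tibble(
      id = id, chimera = if (flagged) "flagged" else "clean",
      i1 = i1, i2 = if (is.finite(i2)) i2 else NA_real_,
      parent_a = if (flagged) parent_pool$id[keep[best["a"]]] else NA_character_,
      parent_b = if (flagged) parent_pool$id[keep[best["b"]]] else NA_character_)
  })
}

#' Run an external assembler on one bin
#'
#' Optional hook for an external seeded assembler (e.g. a SPAdes-style tool
#' accepting the seed as a trusted contig). The command template may use the
#' placeholders `{r1}`, `{r2}`, `{seed}`, `{outdir}`; it must leave a
#' `contigs.fasta` in `{outdir}`. The contig best containing the seed is
#' selected. Untested in environments without the tool; the built-in extender
#' is the default path.
#'
#' @param bin Paired-read tibble for one seed.
#' @param seed One-row seed tibble.
#' @param command_template Shell command template.
#' @param params [assembly_params()].
#' @return One-row tibble in the [assemble_seed()] layout.
#' @export
external_assembler <- function(bin, seed, command_template,
                               params = assembly_params()) {
  seed_id <- if (!is.null(seed$otu_id)) seed$otu_id[[1]] else seed$id[[1]]
  work <- tempfile("extasm_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  r1 <- file.path(work, "bin_R1.fastq"); r2 <- file.path(work, "bin_R2.fastq")
  write_fastq_pair(bin, r1, r2)
  sf <- file.path(work, "seed.fasta")
  write_fasta(tibble::tibble(id = seed_id, sequence = seed$sequence[[1]]), sf)
  outdir <- file.path(work, "out")
  cmd <- command_template
  cmd <- gsub("{r1}", r1, cmd, fixed = TRUE)
  cmd <- gsub("{r2}", r2, cmd, fixed = TRUE)
  cmd <- gsub("{seed}", sf, cmd, fixed = TRUE)
  cmd <- gsub("{outdir}", outdir, cmd, fixed = TRUE)
  status <- suppressWarnings(system(cmd))
  fail <- tibble::tibble(
    seed_id = seed_id, sequence = NA_character_, length = 0L,
    n_pairs = nrow(bin), n_pairs_used = 0L, seed_start = NA_integer_,
    seed_end = NA_integer_, status = "failed")
  if (status != 0) {
    stop("external assembler failed (exit ", status, "): ", cmd,
         call. = FALSE)
  }
  cf <- file.path(outdir, "contigs.fasta")
  if (!file.exists(cf)) return(fail)
  contigs <- read_fasta(cf)
  if (nrow(contigs) == 0) return(fail)
  aln <- align_seqs(rep(seed$sequence[[1]], nrow(contigs)),
                    contigs$sequence, mode = "local",
                    scoring = params$scoring)
  cover <- (aln$qend - aln$qstart) / nchar(seed$sequence[[1]])
  ok <- which(aln$identity >= 99 & cover >= 0.95)
  if (length(ok) == 0) return(fail)
  bestj <- ok[which.max(aln$score[ok])]
  tibble::tibble(
    seed_id = seed_id, sequence = contigs$sequence[bestj],
    length = nchar(contigs$sequence[bestj]), n_pairs = nrow(bin),
    n_pairs_used = NA_integer_, seed_start = aln$sstart[bestj],
    seed_end = aln$send[bestj], status = "ok")
}
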