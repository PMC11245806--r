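#' Simulation parameters for synthetic communities
#'
#' Builds the parameter list controlling the synthetic-community generator.
#' The defaults describe a desk-scale mock co-sequencing experiment: genomes
#' carrying 1-3 embedded multi-copy 16S genes, per-sample abundances drawn
#' from an exponential distribution (with a tempering exponent producing
#' low-diversity samples), 150 bp paired shotgun reads and merged ~440 nt
#' amplicon reads from a fixed window of the 16S gene (emulating a merged
#' V3-V4 product).
#'
#' @param n_genomes Number of genomes in the community.
#' @param n_samples_low,n_samples_high Number of low- and high-diversity
#'   samples.
#' @param shotgun_read_len Shotgun read length (nt).
#' @param amplicon_read_len Nominal amplicon instrument read length (nt);
#'   amplicons are emitted as already-merged products of the amplicon window,
#'   so this is informational.
#' @param n_shotgun_pairs Shotgun read pairs per sample.
#' @param n_amplicon_reads Amplicon reads per sample.
#' @param error_rate Per-base substitution error rate for shotgun reads
#'   (in \[0, 0.1\]).
#' @param amplicon_error_rate Per-base substitution error rate for amplicon
#'   reads. Defaults to 0: seeds represent denoised OTU centroids, so
#'   amplicon sequencing error mainly inflates dereplication and is off by
#'   default.
#' @param indel_rate Per-base indel rate for shotgun reads (default 0;
#'   substitution-only error model by default).
#' @param insert_mean,insert_sd Fragment (insert) length distribution,
#'   truncated at `2 * shotgun_read_len - 20`.
#' @param amplicon_region Length-2 integer vector, 0-based half-open window
#'   within the 16S gene excised as the amplicon (window length must be in
#'   \[350, 500\]).
#' @param sixteen_s_len Length of the 16S gene template (nt).
#' @param conserved_len,variable_len Lengths of the alternating conserved and
#'   variable blocks of the 16S template.
#' @param var_div_min,var_div_max Per-genome per-base substitution rate range
#'   applied to variable blocks (drawn uniformly per genome), spreading
#'   inter-genome 16S identities over roughly 85-99%.
#' @param intra_copy_rate Per-base substitution rate between 16S copies
#'   within one genome (keeps copies >= 99% mutually identical).
#' @param max_loci Maximum 16S copies per genome (1 to `max_loci`).
#' @param backbone_factor Backbone length as a multiple of the 16S length,
#'   so that most shotgun reads are non-16S.
#' @param low_diversity_power Exponent applied to exponential draws in
#'   low-diversity mode (>1 makes the top genome dominate).
#' @param rng_seed Integer seed fixing all simulator output.
#' @return A named list of class `seedrecon_sim_params`.
#' @export
sim_params <- function(n_genomes = 20, n_samples_low = 4, n_samples_high = 4,
                       shotgun_read_len = 150, amplicon_read_len = 300,
                       n_shotgun_pairs = 50000, n_amplicon_reads = 2000,
                       error_rate = 0.005, amplicon_error_rate = 0,
                       indel_rate = 0,
                       insert_mean = 300, insert_sd = 30,
                       amplicon_region = c(420L, 860L),
                       sixteen_s_len = 1550,
                       conserved_len = 90, variable_len = 50,
                       var_div_min = 0.04, var_div_max = 0.15,
                       intra_copy_rate = 0.002, max_loci = 3,
                       backbone_factor = 20,
                       low_diversity_power = 3,
                       rng_seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_genomes >= 2,
    p$shotgun_read_len > 0, p$amplicon_read_len > 0,
    p$error_rate >= 0, p$error_rate <= 0.1,
    p$amplicon_error_rate >= 0, p$amplicon_error_rate <= 0.1,
    p$indel_rate >= 0,
    length(p$amplicon_region) == 2
  )
  w <- p$amplicon_region[2] - p$amplicon_region[1]
  if (w < 350 || w > 500) {
    stop("amplicon window length must be in [350, 500], got ", w,
         call. = FALSE)
  }
  if (p$amplicon_region[2] > p$sixteen_s_len) {
    stop("amplicon window exceeds the 16S gene length", call. = FALSE)
  }
  class(p) <- "seedrecon_sim_params"
  p
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at given 1-based positions with random different bases
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

mutate_at_rate <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  mutate_positions(seq, sample.int(n, k))
}

#' Construct synthetic genomes with embedded multi-copy 16S genes
#'
#' A 16S template of alternating conserved blocks (shared across genomes) and
#' variable blocks (mutated per genome at a genome-specific rate) is built
#' once; each genome receives 1 to `max_loci` copies (copies within a genome
#' are >= 99% mutually identical), embedded verbatim in a random backbone at
#' recorded positions, with the backbone at least `backbone_factor` times the
#' 16S length so most shotgun reads are non-16S.
#'
#' Uses the current RNG state; call `set.seed()` first (or use
#' [simulate_community()], which seeds from its parameters).
#'
#' @param params A [sim_params()] list.
#' @return List with `genomes` (tibble: `genome_id`, `sequence`, `length`)
#'   and `loci` (tibble: `genome_id`, `locus`, `start`, `end`, `sequence`;
#'   coordinates 0-based half-open).
#' @export
build_genomes <- function(params) {
  stopifnot(params$n_genomes >= 2)
  L <- params$sixteen_s_len
  # block layout: C V C V ... truncated to L; TRUE = variable position
  block <- c(rep(FALSE, params$conserved_len), rep(TRUE, params$variable_len))
  is_var <- rep(block, length.out = L)
  template <- random_dna(L)
  var_pos <- which(is_var)

  ids <- sprintf("G%03d", seq_len(params$n_genomes))
  rates <- stats::runif(params$n_genomes, params$var_div_min, params$var_div_max)

  genomes <- vector("list", params$n_genomes)
  loci <- vector("list", params$n_genomes)
  for (g in seq_len(params$n_genomes)) {
    k <- stats::rbinom(1, length(var_pos), rates[g])
    gene <- mutate_positions(template, sample(var_pos, k))
    n_loci <- sample.int(params$max_loci, 1)
    copies <- c(gene, vapply(seq_len(max(0, n_loci - 1)), function(i) {
      mutate_at_rate(gene, params$intra_copy_rate)
    }, character(1)))
    backbone_len <- params$backbone_factor * L
    spacer <- backbone_len %/% (n_loci + 1)
    parts <- character(0); pos <- 0L
    starts <- integer(n_loci)
    for (i in seq_len(n_loci)) {
      sp <- random_dna(spacer)
      parts <- c(parts, sp, copies[i])
      starts[i] <- pos + spacer
      pos <- pos + spacer + nchar(copies[i])
    }
    parts <- c(parts, random_dna(backbone_len - n_loci * spacer))
    genomes[[g]] <- tibble::tibble(
      genome_id = ids[g],
      sequence = paste(parts, collapse = ""))
    loci[[g]] <- tibble::tibble(
      genome_id = ids[g], locus = seq_len(n_loci),
      start = starts, end = starts + nchar(copies),
      sequence = copies)
  }
  genomes <- dplyr::bind_rows(genomes)
  genomes$length <- nchar(genomes$sequence)
  list(genomes = genomes, loci = dplyr::bind_rows(loci))
}

#' Draw a per-sample relative abundance vector
#'
#' Abundances are i.i.d. exponential draws, normalized to sum to one. In
#' low-diversity mode the draws are first raised to a power > 1 (exponent
#' tempering), so that the most abundant genomes dominate while the
#' exponential origin of the distribution is preserved.
#'
#' @param n_genomes Number of genomes.
#' @param diversity_mode `"low"` or `"high"`.
#' @param power Tempering exponent used in low mode.
#' @return Numeric vector of length `n_genomes`, positive, summing to 1.
#' @export
sample_abundances <- function(n_genomes, diversity_mode = c("high", "low"),
                              power = 3) {
  diversity_mode <- match.arg(diversity_mode)
  stopifnot(n_genomes >= 1)
  x <- stats::rexp(n_genomes)
  if (diversity_mode == "low") x <- x^power
  x / sum(x)
}

#' Build a full synthetic community
#'
#' Seeds the RNG from `params$rng_seed`, constructs the genome set and draws
#' an independent abundance vector for every sample (low-diversity samples
#' first). All downstream simulator calls on the returned object are
#' reproducible given the same parameters.
#'
#' @param params A [sim_params()] list.
#' @return An object of class `seedrecon_community`: list with `params`,
#'   `genomes`, `loci` and `abundances` (tibble: `sample_id`, `diversity`,
#'   `genome_id`, `abundance`).
#' @export
simulate_community <- function(params = sim_params()) {
  set.seed(params$rng_seed)
  gen <- build_genomes(params)
  samples <- tibble::tibble(
    sample_id = c(sprintf("L%02d", seq_len(params$n_samples_low)),
                  sprintf("H%02d", seq_len(params$n_samples_high))),
    diversity = c(rep("low", params$n_samples_low),
                  rep("high", params$n_samples_high)))
  ab <- purrr::pmap_dfr(samples, function(sample_id, diversity) {
    a <- sample_abundances(params$n_genomes, diversity,
                           power = params$low_diversity_power)
    tibble::tibble(
      sample_id = sample_id, diversity = diversity,
      genome_id = gen$genomes$genome_id,
      abundance = a)
  })
  structure(list(params = params, genomes = gen$genomes, loci = gen$loci,
                 abundances = ab),
            class = "seedrecon_community")
}

#' @export
print.seedrecon_community <- function(x, ...) {
  cat("Synthetic community:", nrow(x$genomes), "genomes,",
      nrow(x$loci), "16S loci,",
      length(unique(x$abundances$sample_id)), "samples\n")
  invisible(x)
}

apply_subst_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    seqs[i] <- mutate_positions(seqs[i], sample.int(lens[i], nerr[i]))
  }
  seqs
}

apply_indels <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nev <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nev > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    for (k in seq_len(nev[i])) {
      p <- sample.int(length(chars), 1)
      if (stats::runif(1) < 0.5 && length(chars) > 1) {
        chars <- chars[-p]
      } else {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = p)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate tagged paired shotgun reads for one sample
#'
#' Fragments are drawn genome-proportionally to abundance x genome length;
#' insert lengths are Normal(`insert_mean`, `insert_sd`) truncated at
#' `2 * read_len - 20`; mates are the two fragment ends with mate 2
#' reverse-complemented; substitution errors are applied at `error_rate`.
#' Every read header carries a `genome=` tag, plus `locus=` when the fragment
#' overlaps an rRNA locus.
#'
#' Uses the current RNG state (see [simulate_community()] for end-to-end
#' seeding; seed explicitly when calling stages individually).
#'
#' @param community A `seedrecon_community`.
#' @param sample_id Sample to simulate (must exist in the community).
#' @param n_pairs Number of read pairs (default `params$n_shotgun_pairs`).
#' @return Paired-read tibble in the [read_fastq_pair()] layout.
#' @export
simulate_shotgun <- function(community, sample_id,
                             n_pairs = community$params$n_shotgun_pairs) {
  if (n_pairs < 1) stop("requested pairs must be >= 1", call. = FALSE)
  p <- community$params
  ab <- dplyr::filter(community$abundances, .data$sample_id == !!sample_id)
  if (nrow(ab) == 0) stop("unknown sample: ", sample_id, call. = FALSE)
  glen <- community$genomes$length[match(ab$genome_id,
                                         community$genomes$genome_id)]
  w <- ab$abundance * glen
  gidx <- sample.int(nrow(ab), n_pairs, replace = TRUE, prob = w / sum(w))
  gid <- ab$genome_id[gidx]
  gseq <- community$genomes$sequence[match(gid, community$genomes$genome_id)]
  gl <- glen[gidx]
  min_ins <- 2L * p$shotgun_read_len - 20L
  ins <- pmax(min_ins, round(stats::rnorm(n_pairs, p$insert_mean, p$insert_sd)))
  ins <- pmin(ins, gl)
  start <- floor(stats::runif(n_pairs) * (gl - ins + 1))  # 0-based
  seq1 <- substring(gseq, start + 1, start + p$shotgun_read_len)
  seq2 <- revcomp(substring(gseq, start + ins - p$shotgun_read_len + 1,
                            start + ins))
  seq1 <- apply_subst_errors(seq1, p$error_rate)
  seq2 <- apply_subst_errors(seq2, p$error_rate)
  if (p$indel_rate > 0) {
    seq1 <- apply_indels(seq1, p$indel_rate)
    seq2 <- apply_indels(seq2, p$indel_rate)
  }
  # provenance: locus tag when the fragment overlaps an rRNA locus
  loci <- community$loci
  frag_end <- start + ins
  locus <- rep(NA_integer_, n_pairs)
  for (g in unique(gid)) {
    lg <- loci[loci$genome_id == g, ]
    sel <- which(gid == g)
    for (j in seq_len(nrow(lg))) {
      ov <- sel[start[sel] < lg$end[j] & frag_end[sel] > lg$start[j]]
      locus[ov[is.na(locus[ov])]] <- lg$locus[j]
    }
  }
  desc <- ifelse(is.na(locus), paste0("genome=", gid),
                 paste0("genome=", gid, " locus=", locus))
  tibble::tibble(
    pair_id = sprintf("%s_p%07d", sample_id, seq_len(n_pairs)),
    sample_id = sample_id,
    seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
    seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
    desc1 = desc, desc2 = desc,
    genome = gid, locus = locus)
}

#' Simulate merged amplicon reads for one sample
#'
#' For each read a genome is picked proportionally to abundance, one of its
#' 16S loci uniformly, and the amplicon window excised; reads are emitted as
#' already-merged single sequences (the paired-merged V3-V4 product), with
#' substitution errors at `amplicon_error_rate` and `genome=` header tags.
#'
#' @inheritParams simulate_shotgun
#' @param n_reads Number of amplicon reads.
#' @return Tibble: `read_id`, `sample_id`, `sequence`, `quality`,
#'   `description`, `genome`, `locus`.
#' @export
simulate_amplicons <- function(community, sample_id,
                               n_reads = community$params$n_amplicon_reads) {
  p <- community$params
  win <- p$amplicon_region
  bad <- community$loci$end - community$loci$start < win[2]
  if (any(bad)) {
    stop("amplicon window exceeds a 16S locus (genome ",
         community$loci$genome_id[bad][1], ")", call. = FALSE)
  }
  ab <- dplyr::filter(community$abundances, .data$sample_id == !!sample_id)
  if (nrow(ab) == 0) stop("unknown sample: ", sample_id, call. = FALSE)
  gidx <- sample.int(nrow(ab), n_reads, replace = TRUE, prob = ab$abundance)
  gid <- ab$genome_id[gidx]
  loci <- community$loci
  locus <- vapply(gid, function(g) {
    ls <- loci$locus[loci$genome_id == g]
    ls[sample.int(length(ls), 1)]
  }, integer(1), USE.NAMES = FALSE)
  key <- paste(gid, locus)
  lseq <- loci$sequence[match(key, paste(loci$genome_id, loci$locus))]
  amp <- substring(lseq, win[1] + 1, win[2])
  amp <- apply_subst_errors(amp, p$amplicon_error_rate)
  tibble::tibble(
    read_id = sprintf("%s_a%07d", sample_id, seq_len(n_reads)),
    sample_id = sample_id,
    sequence = amp,
    quality = strrep("I", nchar(amp)),
    description = paste0("genome=", gid, " locus=", locus),
    genome = gid, locus = locus)
}

#' Ground-truth tables for a simulated community
#'
#' Deterministic given the community (no RNG use): the truth 16S set (one
#' record per locus, tagged with genome and locus), and the per-sample
#' abundance table. Downstream evaluation consumes only these plus the tagged
#' reads.
#'
#' @param community A `seedrecon_community`.
#' @param dir Optional directory; when given, writes `truth_16s.fasta` and
#'   `abundances.tsv` there.
#' @return List with `truth_16s` (sequence tibble with `genome`, `locus`
#'   columns) and `abundances` (wide tibble, samples x genomes).
#' @export
truth_tables <- function(community, dir = NULL) {
  truth <- tibble::tibble(
    id = sprintf("%s_16S_%d", community$loci$genome_id, community$loci$locus),
    description = paste0("genome=", community$loci$genome_id,
                         " locus=", community$loci$locus),
    sequence = community$loci$sequence,
    genome = community$loci$genome_id,
    locus = community$loci$locus)
  ab_wide <- tidyr::pivot_wider(
    community$abundances[, c("sample_id", "genome_id", "abundance")],
    names_from = "genome_id", values_from = "abundance")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(truth, file.path(dir, "truth_16s.fasta"))
    utils::write.table(ab_wide, file.path(dir, "abundances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(truth_16s = truth, abundances = ab_wide)
}
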