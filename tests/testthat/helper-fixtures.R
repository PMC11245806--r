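# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions with different bases
mutate_k <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Deterministic, nested even-tiling read pairs over a region: the n requested
# fragment starts are every (80/n)-th of 80 evenly spaced anchors, so bins of
# 5/10/20/40/80 pairs are nested subsets of the same layout.
tiling_pairs <- function(region, n, read_len = 150, insert = 300,
                         n_max = 80) {
  stopifnot(n_max %% n == 0)
  L <- nchar(region)
  anchors <- round(seq(0, L - insert, length.out = n_max))
  starts <- anchors[seq(1, n_max, by = n_max %/% n)]
  tibble::tibble(
    pair_id = sprintf("t%03d", seq_along(starts)),
    sample_id = "T",
    seq1 = substring(region, starts + 1, starts + read_len),
    qual1 = strrep("I", read_len),
    seq2 = revcomp(substring(region, starts + insert - read_len + 1,
                             starts + insert)),
    qual2 = strrep("I", read_len))
}

# small community cache shared across test files (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

small_community <- function() {
  if (is.null(.fixture_env$comm)) {
    p <- sim_params(n_genomes = 6, n_samples_low = 1, n_samples_high = 1,
                    n_shotgun_pairs = 800, n_amplicon_reads = 300,
                    error_rate = 0, amplicon_error_rate = 0, rng_seed = 301)
    .fixture_env$comm <- simulate_community(p)
    .fixture_env$truth <- truth_tables(.fixture_env$comm)
  }
  list(comm = .fixture_env$comm, truth = .fixture_env$truth)
}

# independent brute-force replay of the greedy clustering scan: all-pairs
# identity matrix first, then the documented ordering and first-fit rule
oracle_greedy <- function(seqs_with_counts, threshold) {
  ord <- order(-seqs_with_counts$total, seqs_with_counts$sequence)
  seqs <- seqs_with_counts$sequence[ord]
  n <- length(seqs)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) idm[i, j] <- pair_identity(seqs[i], seqs[j])
    }
  }
  centroids <- integer(0)
  member <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (ci in seq_along(centroids)) {
      if (idm[i, centroids[ci]] >= threshold * 100) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, i); hit <- length(centroids) }
    member[i] <- hit
  }
  split(seqs, member)
}

# one truth gene with genomic flanks, its seed window; reads via
# tiling_pairs()
asm_fixture <- function() {
  if (is.null(.fixture_env$asm)) {
    fx <- small_community()
    gene <- fx$truth$truth_16s$sequence[1]
    win <- fx$comm$params$amplicon_region
    set.seed(501)
    region <- paste0(rand_dna(100), gene, rand_dna(100))
    .fixture_env$asm <- list(
      gene = gene,
      region = region,
      seed = tibble::tibble(otu_id = "SEED1",
                            sequence = substr(gene, win[1] + 1, win[2])),
      truth = fx$truth$truth_16s[1, , drop = FALSE])
  }
  .fixture_env$asm
}

# seeds derived from the small community's amplicons
small_seedset <- function() {
  if (is.null(.fixture_env$seeds)) {
    fx <- small_community()
    samples <- unique(fx$comm$abundances$sample_id)
    amps <- dplyr::bind_rows(lapply(seq_along(samples), function(i) {
      set.seed(400 + i)
      simulate_amplicons(fx$comm, samples[i])
    }))
    cl <- cluster_otus(amps)
    .fixture_env$seeds <- cl$seeds
    .fixture_env$otu_table <- cl$otu_table
    .fixture_env$abundance <- otu_rel_abundance(cl$otu_table)
  }
  list(seeds = .fixture_env$seeds, otu_table = .fixture_env$otu_table,
       abundance = .fixture_env$abundance)
}
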