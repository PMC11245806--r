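test_that("genomes embed their 16S loci verbatim with copies >= 99% identical", {
  fx <- small_community()
  comm <- fx$comm
  for (i in seq_len(nrow(comm$loci))) {
    l <- comm$loci[i, ]
    g <- comm$genomes$sequence[comm$genomes$genome_id == l$genome_id]
    expect_equal(substr(g, l$start + 1, l$end), l$sequence)
  }
  # intra-genome copy identity
  multi <- comm$loci |> dplyr::count(genome_id) |> dplyr::filter(n > 1)
  for (g in multi$genome_id) {
    copies <- comm$loci$sequence[comm$loci$genome_id == g]
    expect_gte(pair_identity(copies[1], copies[2]), 99)
  }
  # backbone dominates: genomes much longer than their rRNA content
  expect_true(all(comm$genomes$length >=
                    20 * sim_params()$sixteen_s_len))
})

test_that("inter-genome 16S identities are spread below the intra radius", {
  fx <- small_community()
  first <- fx$truth$truth_16s |>
    dplyr::group_by(genome) |> dplyr::slice(1) |> dplyr::ungroup()
  pairs <- utils::combn(nrow(first), 2)
  idn <- vapply(seq_len(ncol(pairs)), function(j) {
    pair_identity(first$sequence[pairs[1, j]], first$sequence[pairs[2, j]])
  }, numeric(1))
  expect_lt(min(idn), 95)
  expect_true(all(idn < 99))
})

test_that("abundance draws are positive, normalized and entropy-ordered", {
  set.seed(5)
  expect_equal(sample_abundances(1, "high"), 1)
  for (mode in c("low", "high")) {
    a <- sample_abundances(25, mode)
    expect_true(all(a > 0))
    expect_equal(sum(a), 1)
  }
  shannon <- function(p) -sum(p * log(p))
  set.seed(6)
  h_low <- replicate(200, shannon(sample_abundances(40, "low")))
  h_high <- replicate(200, shannon(sample_abundances(40, "high")))
  expect_lt(mean(h_low), mean(h_high))
})

test_that("zero-error shotgun mates are exact genome substrings, tagged", {
  fx <- small_community()
  comm <- fx$comm
  s <- comm$abundances$sample_id[1]
  set.seed(77)
  sh <- simulate_shotgun(comm, s, n_pairs = 60)
  expect_true(all(!is.na(sh$genome)))
  for (i in seq_len(20)) {
    g <- comm$genomes$sequence[comm$genomes$genome_id == sh$genome[i]]
    expect_true(grepl(sh$seq1[i], g, fixed = TRUE))
    expect_true(grepl(revcomp(sh$seq2[i]), g, fixed = TRUE))
  }
  expect_error(simulate_shotgun(comm, s, n_pairs = 0), "pairs")
  expect_error(simulate_shotgun(comm, "nope"), "unknown sample")
})

test_that("shotgun genome shares follow abundance x length weights", {
  fx <- small_community()
  comm <- fx$comm
  s <- comm$abundances$sample_id[2]
  set.seed(88)
  sh <- simulate_shotgun(comm, s, n_pairs = 6000)
  ab <- comm$abundances[comm$abundances$sample_id == s, ]
  w <- ab$abundance * comm$genomes$length[match(ab$genome_id,
                                                comm$genomes$genome_id)]
  expected <- w / sum(w)
  top <- ab$genome_id[which.max(expected)]
  p <- expected[which.max(expected)]
  obs <- mean(sh$genome == top)
  se <- sqrt(p * (1 - p) / 6000)
  expect_lt(abs(obs - p), 3 * se + 1e-9)
})

test_that("rRNA-overlap tagging matches the genomic rRNA fraction", {
  fx <- small_community()
  comm <- fx$comm
  s <- comm$abundances$sample_id[1]
  set.seed(99)
  sh <- simulate_shotgun(comm, s, n_pairs = 4000)
  # expected fraction of fragments overlapping a locus, abundance-weighted
  ab <- comm$abundances[comm$abundances$sample_id == s, ]
  glen <- comm$genomes$length[match(ab$genome_id, comm$genomes$genome_id)]
  w <- ab$abundance * glen / sum(ab$abundance * glen)
  frag <- 300
  p_per_genome <- vapply(seq_len(nrow(ab)), function(i) {
    lg <- comm$loci[comm$loci$genome_id == ab$genome_id[i], ]
    sum(lg$end - lg$start + frag) / glen[i]
  }, numeric(1))
  p <- sum(w * pmin(p_per_genome, 1))
  obs <- mean(!is.na(sh$locus))
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(obs - p), 4 * se + 0.01)
})

test_that("amplicons excise the window exactly at zero error", {
  fx <- small_community()
  comm <- fx$comm
  s <- comm$abundances$sample_id[1]
  set.seed(111)
  amp <- simulate_amplicons(comm, s, n_reads = 50)
  win <- comm$params$amplicon_region
  expect_true(all(nchar(amp$sequence) == win[2] - win[1]))
  for (i in 1:10) {
    l <- comm$loci[comm$loci$genome_id == amp$genome[i] &
                     comm$loci$locus == amp$locus[i], ]
    expect_equal(amp$sequence[i],
                 substr(l$sequence, win[1] + 1, win[2]))
  }
})

test_that("amplicon abundance ranking tracks genome abundances", {
  fx <- small_community()
  comm <- fx$comm
  s <- comm$abundances$sample_id[2]
  set.seed(112)
  amp <- simulate_amplicons(comm, s, n_reads = 5000)
  obs <- table(factor(amp$genome, levels = sort(unique(comm$abundances$genome_id))))
  ab <- comm$abundances[comm$abundances$sample_id == s, ]
  ab <- ab[order(ab$genome_id), ]
  rho <- stats::cor(as.numeric(obs), ab$abundance, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("the amplicon window length bound is enforced at setup", {
  expect_error(sim_params(amplicon_region = c(0L, 300L)), "\\[350, 500\\]")
  expect_error(sim_params(amplicon_region = c(1300L, 1750L)), "exceeds")
})

test_that("simulation is byte-deterministic given the seed", {
  p <- sim_params(n_genomes = 4, n_samples_low = 1, n_samples_high = 1,
                  n_shotgun_pairs = 50, n_amplicon_reads = 30,
                  error_rate = 0.01, rng_seed = 555)
  run <- function() {
    comm <- simulate_community(p)
    set.seed(1); sh <- simulate_shotgun(comm, comm$abundances$sample_id[1])
    set.seed(2); am <- simulate_amplicons(comm, comm$abundances$sample_id[1])
    d <- tempfile(); truth_tables(comm, dir = d)
    list(sh = sh, am = am,
         truth = readLines(file.path(d, "truth_16s.fasta")),
         ab = readLines(file.path(d, "abundances.tsv")))
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})

test_that("error model injects substitutions at the configured rate", {
  fx <- small_community()
  comm2 <- fx$comm
  comm2$params$error_rate <- 0.02
  s <- comm2$abundances$sample_id[1]
  set.seed(121)
  sh <- simulate_shotgun(comm2, s, n_pairs = 400)
  # compare reads to their source genomes by alignment
  idx <- sample.int(400, 40)
  idn <- vapply(idx, function(i) {
    g <- comm2$genomes$sequence[comm2$genomes$genome_id == sh$genome[i]]
    max(align_seqs(sh$seq1[i], g, mode = "local")$identity, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(idn), 100)
  expect_gt(mean(idn), 95)
})
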