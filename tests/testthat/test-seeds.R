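test_that("identical reads collapse to one OTU with summed counts", {
  amp <- tibble::tibble(sequence = rep(strrep("ACGT", 50), 3),
                        sample_id = c("S1", "S1", "S2"))
  cl <- cluster_otus(amp)
  expect_equal(nrow(cl$seeds), 1)
  expect_equal(sum(cl$otu_table$S1, cl$otu_table$S2), 3)
})

test_that("sequences below the identity radius found separate OTUs", {
  base <- rand_dna(400, seed = 31)
  far <- mutate_k(base, 20, seed = 32)   # 95% identity
  near <- mutate_k(base, 2, seed = 33)   # 99.5% identity
  amp <- tibble::tibble(sequence = c(base, base, far, near),
                        sample_id = "S1")
  cl <- cluster_otus(amp, identity = 0.99)
  expect_equal(nrow(cl$seeds), 2)
  # the dominant exact sequence is the first centroid
  expect_equal(cl$seeds$sequence[1], base)
  expect_error(cluster_otus(amp[0, ]), "no amplicon")
})

test_that("greedy clustering matches the brute-force oracle on a random mix", {
  set.seed(35)
  bases <- replicate(4, rand_dna(300))
  seqs <- unlist(lapply(bases, function(b) {
    c(b, replicate(3, mutate_k(b, sample(1:12, 1))))
  }))
  counts <- sample(1:5, length(seqs), replace = TRUE)
  amp <- tibble::tibble(
    sequence = rep(seqs, counts),
    sample_id = sample(c("S1", "S2"), sum(counts), replace = TRUE))
  cl <- cluster_otus(amp, identity = 0.97)
  derep <- amp |>
    dplyr::count(sequence, name = "total")
  oracle <- oracle_greedy(derep, 0.97)
  expect_equal(nrow(cl$seeds), length(oracle))
  # identical partitions: compare the set of member sets
  mine <- split(cl$membership$sequence, cl$membership$otu_id)
  canon <- function(p) sort(vapply(p, function(m) {
    paste(sort(m), collapse = "|")
  }, character(1)))
  expect_equal(canon(mine), canon(oracle), ignore_attr = TRUE)
  # and identical centroid sets
  oracle_centroids <- sort(unname(vapply(oracle, `[[`, character(1), 1)))
  expect_equal(sort(cl$seeds$sequence), oracle_centroids)
})

test_that("every member attains the radius identity to its centroid", {
  fx <- small_seedset()
  comm <- small_community()$comm
  s <- comm$abundances$sample_id[1]
  set.seed(401)
  amp <- simulate_amplicons(comm, s, n_reads = 120)
  cl <- cluster_otus(amp)
  # re-derive membership: each unique read must be within 99% of some centroid
  for (sq in unique(amp$sequence)) {
    idn <- vapply(cl$seeds$sequence, function(cs) pair_identity(sq, cs),
                  numeric(1))
    expect_gte(max(idn), 99)
  }
})

test_that("novelty filter separates known and novel seeds", {
  ref_seq <- rand_dna(1500, seed = 51)
  seeds <- tibble::tibble(
    otu_id = c("OTU_A", "OTU_B", "OTU_C"),
    sequence = c(substr(ref_seq, 301, 740),          # exact reference piece
                 mutate_k(substr(ref_seq, 301, 740), 7, seed = 52),  # 98.4%
                 rand_dna(440, seed = 53)))          # unrelated
  reference <- tibble::tibble(id = "REF1", description = "",
                              sequence = ref_seq)
  fk <- filter_known(seeds, reference, identity = 0.99)
  expect_equal(fk$known$otu_id, "OTU_A")
  expect_equal(fk$known$matched_ref, "REF1")
  expect_setequal(fk$novel$otu_id, c("OTU_B", "OTU_C"))
  # empty reference leaves everything novel
  fk0 <- filter_known(seeds, reference[0, ])
  expect_equal(nrow(fk0$novel), 3)
})

test_that("sample selection walks the ranked OTU list", {
  # top-2 OTUs peak in the same sample; walk continues to OTU 3's sample
  tab <- tibble::tibble(
    otu_id = c("OTU_1", "OTU_2", "OTU_3"),
    S1 = c(50L, 40L, 1L), S2 = c(10L, 8L, 9L))
  expect_equal(select_samples(tab, 2), c("S1", "S2"))
  expect_equal(select_samples(tab, 1), "S1")
  expect_error(select_samples(tab, 3), "exceeds")
})

test_that("sample selection matches an exhaustive hand walk on a fixture", {
  set.seed(61)
  tab <- tibble::tibble(otu_id = sprintf("OTU_%d", 1:5))
  for (s in c("S1", "S2", "S3", "S4")) tab[[s]] <- sample(0:40, 5)
  # brute-force oracle
  rel <- otu_rel_abundance(tab)
  ranked <- rel |>
    dplyr::group_by(otu_id) |>
    dplyr::summarise(
      m = max(rel_abundance),
      top = min(sample_id[rel_abundance == max(rel_abundance)])) |>
    dplyr::arrange(dplyr::desc(m), otu_id)
  walk <- character(0)
  for (i in seq_len(nrow(ranked))) {
    if (!(ranked$top[i] %in% walk)) walk <- c(walk, ranked$top[i])
  }
  for (n in 1:min(3, length(walk))) {
    expect_equal(select_samples(tab, n), walk[seq_len(n)])
  }
})

test_that("seed selection ranks by abundance with documented tie-breaks", {
  seeds <- tibble::tibble(
    otu_id = sprintf("OTU_%d", 1:4),
    sequence = replicate(4, rand_dna(400)))
  tab <- tibble::tibble(
    otu_id = seeds$otu_id,
    S1 = c(10L, 5L, 10L, 1L), S2 = c(0L, 20L, 0L, 2L))
  out <- select_seeds(seeds, tab, c("S1", "S2"), K = 3)
  expect_equal(nrow(out), 3)
  # oracle sort on (max rel abundance, total count, id)
  rel <- otu_rel_abundance(tab)
  st <- rel |>
    dplyr::group_by(otu_id) |>
    dplyr::summarise(m = max(rel_abundance), tot = sum(count)) |>
    dplyr::arrange(dplyr::desc(m), dplyr::desc(tot), otu_id)
  expect_equal(out$otu_id, st$otu_id[1:3])
  # K larger than available returns everything ranked
  out_all <- select_seeds(seeds, tab, c("S1", "S2"), K = 50)
  expect_equal(out_all$otu_id, st$otu_id)
  # abundance 0.10 vs 0.05 ranks the former first
  tab2 <- tibble::tibble(otu_id = c("OTU_1", "OTU_2"),
                         S1 = c(10L, 5L), S2 = c(90L, 95L))
  out2 <- select_seeds(seeds[1:2, ], tab2, "S1", K = 2)
  expect_equal(out2$otu_id[1], "OTU_1")
})

test_that("out-of-bounds seed lengths are excluded with a warning", {
  seeds <- tibble::tibble(otu_id = c("OTU_1", "OTU_2"),
                          sequence = c(rand_dna(400, seed = 71),
                                       rand_dna(80, seed = 72)))
  tab <- tibble::tibble(otu_id = seeds$otu_id, S1 = c(5L, 9L))
  expect_warning(out <- select_seeds(seeds, tab, "S1", K = 10),
                 "length bounds")
  expect_equal(out$otu_id, "OTU_1")
})

test_that("zero-error amplicons from separable genomes give one OTU per variant", {
  fx <- small_community()
  comm <- fx$comm
  samples <- unique(comm$abundances$sample_id)
  set.seed(402)
  amp <- dplyr::bind_rows(lapply(samples, function(s) {
    simulate_amplicons(comm, s, n_reads = 200)
  }))
  cl <- cluster_otus(amp)
  # each OTU centroid equals one truth window; cluster count equals the
  # number of distinct windows merged at the 99% radius
  win <- comm$params$amplicon_region
  truths <- unique(substr(comm$loci$sequence, win[1] + 1, win[2]))
  expect_true(all(cl$seeds$sequence %in% truths))
  expect_lte(nrow(cl$seeds), length(truths))
  expect_gte(nrow(cl$seeds), length(unique(comm$loci$genome_id)))
})
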