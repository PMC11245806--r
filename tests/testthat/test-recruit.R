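make_seed <- function(n = 440, seed = 201) {
  tibble::tibble(otu_id = "OTU_0001", sequence = rand_dna(n, seed = seed))
}

pair_row <- function(seq1, seq2, id = "p1", sample = "S1") {
  tibble::tibble(pair_id = id, sample_id = sample,
                 seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
                 seq2 = seq2, qual2 = strrep("I", nchar(seq2)))
}

test_that("exact substrings hit at 100% identity, full length", {
  seeds <- make_seed()
  read <- substr(seeds$sequence, 101, 250)
  pairs <- pair_row(read, revcomp(substr(seeds$sequence, 201, 350)))
  hits <- align_to_seeds(pairs, seeds)
  expect_equal(nrow(hits), 2)
  expect_true(all(hits$identity == 100))
  expect_true(all(hits$aln_len == 150))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$seed_start[hits$mate == 1], 100)
})

test_that("identity threshold admits 3 substitutions in 150 nt, not 4", {
  seeds <- make_seed()
  r3 <- mutate_k(substr(seeds$sequence, 101, 250), 3, seed = 202)
  r4 <- mutate_k(substr(seeds$sequence, 101, 250), 4, seed = 203)
  pairs <- pair_row(r3, r4)
  hits <- align_to_seeds(pairs, seeds, recruit_params(min_identity = 98))
  # mate 1: 147/150 = 98.0 passes; mate 2 may pass only via a trimmed local
  # alignment, never at full length
  h1 <- hits[hits$mate == 1, ]
  expect_equal(h1$identity, 98)
  h2 <- hits[hits$mate == 2, ]
  if (nrow(h2) > 0) expect_lt(h2$aln_len, 150)
})

test_that("prefilter on and off give identical geometry-passing hit sets", {
  fx <- small_community()
  comm <- fx$comm
  sx <- small_seedset()
  s <- comm$abundances$sample_id[1]
  set.seed(210)
  pairs <- simulate_shotgun(comm, s, n_pairs = 200)
  params <- recruit_params()
  h_on <- align_to_seeds(pairs, sx$seeds, params, prefilter = TRUE)
  h_off <- align_to_seeds(pairs, sx$seeds, params, prefilter = FALSE)
  g_on <- h_on[geometry_pass(h_on, params), ]
  g_off <- h_off[geometry_pass(h_off, params), ]
  expect_equal(g_on, g_off)
})

test_that("geometry rule accepts contained and overhanging reads only", {
  params <- recruit_params()
  base <- tibble::tibble(
    read_id = "r", mate = 1L, seed_id = "s", identity = 100,
    aln_len = 150L, mismatch = 0L, gapopen = 0L,
    read_start = 0L, read_end = 150L, seed_start = 100L, seed_end = 250L,
    strand = "+", score = 300L, read_len = 150L, seed_len = 440L)
  # (a) fully aligned read in the seed interior
  expect_true(geometry_pass(base, params))
  # (b) 3' overhang: alignment reaches the seed end, 60 nt hang off
  over <- base
  over$read_end <- 90L; over$aln_len <- 90L
  over$seed_start <- 350L; over$seed_end <- 440L
  expect_true(geometry_pass(over, params))
  # same overhang on the minus strand: unaligned part is the forward prefix
  over_m <- over; over_m$strand <- "-"
  over_m$read_start <- 60L; over_m$read_end <- 150L
  expect_true(geometry_pass(over_m, params))
  # internal partial alignment: 40 nt unaligned at both read ends, mid-seed
  part <- base
  part$read_start <- 40L; part$read_end <- 110L; part$aln_len <- 70L
  part$seed_start <- 150L; part$seed_end <- 220L
  expect_false(geometry_pass(part, params))
  # unaligned tail points into the seed, not off it
  wrong_side <- over
  wrong_side$seed_start <- 0L; wrong_side$seed_end <- 90L
  expect_false(geometry_pass(wrong_side, params))
})

test_that("pair assignment follows abundance with lexicographic ties", {
  hits <- tibble::tibble(
    read_id = c("p1", "p1", "p2", "p3", "p3", "p3", "p3"),
    mate = c(1L, 2L, 1L, 1L, 1L, 2L, 2L),
    seed_id = c("A", "B", "A", "A", "B", "C", "D"))
  ab <- c(A = 0.04, B = 0.01, C = 0.2, D = 0.1)
  asg <- assign_pairs(hits, "S1", ab, recruit_params(max_matches = 3),
                      pair_ids = c("p1", "p2", "p3", "p4"))
  expect_equal(asg$assigned_seed[asg$pair_id == "p1"], "A")
  expect_true(asg$tie_break_used[asg$pair_id == "p1"])
  expect_equal(asg$assigned_seed[asg$pair_id == "p2"], "A")
  expect_false(asg$tie_break_used[asg$pair_id == "p2"])
  expect_equal(asg$reason[asg$pair_id == "p3"], "too_many_seeds")
  expect_equal(asg$reason[asg$pair_id == "p4"], "no_hit")
  # zero-abundance tie breaks to the lexicographically smallest id
  asg2 <- assign_pairs(hits[1:2, ], "S1", c(X = 1), recruit_params())
  expect_equal(asg2$assigned_seed, "A")
})

test_that("assignment equals a brute-force oracle on a random hit fixture", {
  set.seed(220)
  seeds <- sprintf("OTU_%d", 1:6)
  ab <- stats::setNames(round(stats::runif(6), 3), seeds)
  hits <- tibble::tibble(
    read_id = sprintf("p%02d", sample.int(50, 120, TRUE)),
    mate = sample(1:2, 120, TRUE),
    seed_id = sample(seeds, 120, TRUE))
  params <- recruit_params(max_matches = 3)
  asg <- assign_pairs(hits, "S1", ab, params)
  # oracle: set union per pair, cap, argmax abundance, lexicographic ties
  for (p in unique(hits$read_id)) {
    sds <- sort(unique(hits$seed_id[hits$read_id == p]))
    row <- asg[asg$pair_id == p, ]
    if (length(sds) > 3) {
      expect_equal(row$reason, "too_many_seeds")
    } else {
      a <- ab[sds]
      best <- sds[a == max(a)]
      expect_equal(row$assigned_seed, sort(best)[1])
    }
  }
})

test_that("pair conservation: every pair is assigned or discarded once", {
  fx <- small_community()
  sx <- small_seedset()
  s <- fx$comm$abundances$sample_id[2]
  set.seed(230)
  pairs <- simulate_shotgun(fx$comm, s, n_pairs = 300)
  rec <- recruit_sample(pairs, sx$seeds, sx$abundance)
  asg <- rec$assignments
  expect_equal(nrow(asg), 300)
  expect_equal(anyDuplicated(asg$pair_id), 0)
  expect_equal(sum(asg$reason == "assigned") +
                 sum(asg$reason == "no_hit") +
                 sum(asg$reason == "too_many_seeds"), 300)
  expect_true(all(is.na(asg$assigned_seed[asg$reason != "assigned"])))
})

test_that("identity sweep counts are monotone and zero-error saturates", {
  fx <- small_community()
  sx <- small_seedset()
  s <- fx$comm$abundances$sample_id[1]
  set.seed(240)
  pairs <- simulate_shotgun(fx$comm, s, n_pairs = 400)
  sw <- sweep_identity(pairs, sx$seeds, sx$abundance,
                       thresholds = c(95, 97, 98, 99, 100))
  expect_true(all(diff(sw$n_hits) <= 0))
  # zero-error reads align to their own genome's seed exactly wherever the
  # whole read is contained (cross-genome hits and boundary extensions may
  # legitimately sit below 100%)
  tm <- build_seed_truth(sx$seeds, fx$truth$truth_16s)
  hits <- align_to_seeds(pairs, sx$seeds,
                         recruit_params(min_identity = 95))
  own_genome <- tm$genome[match(hits$seed_id, tm$seed_id)]
  read_genome <- pairs$genome[match(hits$read_id, pairs$pair_id)]
  full_own <- hits[own_genome == read_genome &
                     hits$read_end - hits$read_start == hits$read_len &
                     hits$gapopen == 0, ]
  expect_gt(nrow(full_own), 0)
  # reads from a minority 16S copy can differ from the OTU centroid by a
  # couple of bases, which is exactly why recruitment runs at 98%, one point
  # below the clustering radius
  expect_true(all(full_own$identity >= 98))
  expect_equal(stats::median(full_own$identity), 100)
  # empty threshold list gives an empty report
  expect_equal(nrow(sweep_identity(pairs, sx$seeds, sx$abundance,
                                   numeric(0))), 0)
})

test_that("multiplicity sweep is non-decreasing and matches brute force", {
  set.seed(250)
  seeds <- sprintf("OTU_%d", 1:5)
  ab <- stats::setNames(round(stats::runif(5), 3), seeds)
  hits <- tibble::tibble(
    read_id = sprintf("p%03d", sample.int(100, 260, TRUE)),
    mate = sample(1:2, 260, TRUE),
    seed_id = sample(seeds, 260, TRUE))
  sw <- sweep_multiplicity(hits, "S1", ab, m_values = 1:10)
  expect_true(all(diff(sw$n_assigned) >= 0))
  # brute-force recomputation per m
  for (m in c(1, 3, 7)) {
    n_manual <- sum(vapply(unique(hits$read_id), function(p) {
      length(unique(hits$seed_id[hits$read_id == p])) <= m
    }, logical(1)))
    expect_equal(sw$n_assigned[sw$max_matches == m], n_manual)
  }
  # single-match pairs are constant across m
  uniq <- hits[!duplicated(hits$read_id), ]
  swu <- sweep_multiplicity(uniq, "S1", ab, m_values = c(1, 5, 10))
  expect_equal(length(unique(swu$n_assigned)), 1)
  # a two-seed pair is discarded at m=1, assigned at m=2
  two <- tibble::tibble(read_id = "p", mate = c(1L, 2L),
                        seed_id = c("OTU_1", "OTU_2"))
  sw2 <- sweep_multiplicity(two, "S1", ab, m_values = 1:2)
  expect_equal(sw2$n_assigned, c(0L, 1L))
})

test_that("binning pools samples, prefixes ids and conserves pair counts", {
  pairs <- dplyr::bind_rows(
    pair_row("ACGTACGTAA", "TTTTAAAACC", id = "p1", sample = "S1"),
    pair_row("ACGTACGTCC", "TTTTAAAAGG", id = "p1", sample = "S2"),
    pair_row("ACGTACGTGG", "TTTTAAAATT", id = "p2", sample = "S1"))
  asg <- tibble::tibble(
    pair_id = c("p1", "p1", "p2"), sample_id = c("S1", "S2", "S1"),
    assigned_seed = c("OTU_1", "OTU_1", "OTU_2"),
    reason = "assigned")
  bins <- bin_pairs(asg, pairs)
  expect_equal(bins$seed_id, c("OTU_1", "OTU_2"))
  expect_equal(bins$n_pairs, c(2L, 1L))
  expect_setequal(bins$pairs[[1]]$pair_id, c("S1:p1", "S2:p1"))
  expect_equal(sum(bins$n_pairs), sum(asg$reason == "assigned"))
  # written as per-seed mate files
  d <- tempfile()
  files <- write_bins(bins, d)
  expect_true(all(file.exists(files$r1, files$r2)))
  back <- read_fastq_pair(files$r1[1], files$r2[1], "X")
  expect_equal(nrow(back), 2)
})
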