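#' Default pipeline configuration
#'
#' One declarative list holding every stage's parameters. Defaults equal the
#' established operating point: 99% OTU clustering radius, 98% recruitment
#' identity, multiplicity cap 3, 800 nt minimum reported length, 99% success
#' identity.
#'
#' @return Nested named list of class `seedrecon_config`.
#' @export
default_config <- function() {
  structure(list(
    rng_seed = 1L,
    simulate = list(
      enabled = TRUE,
      n_genomes = 10L, n_samples_low = 2L, n_samples_high = 2L,
      n_shotgun_pairs = 2000L, n_amplicon_reads = 500L,
      error_rate = 0.005, amplicon_error_rate = 0,
      insert_mean = 300, insert_sd = 30),
    seeds = list(
      identity = 0.99, n_samples = 2L, top_k = 300L,
      reference = NULL, filter_known_first = TRUE,
      length_bounds = c(150, 600)),
    recruit = list(
      min_identity = 98, max_matches = 3L, min_aln_len = 50L,
      end_tol = 5L, read_cover_tol = 5L, prefilter_k = 15L),
    assemble = list(
      k = 31L, min_cov = 3L, max_len = 1700L, min_report_len = 800L,
      branch_ratio = 3, min_identity = 96, min_anchor_len = 40L),
    evaluate = list(enabled = TRUE, success_identity = 99),
    chimera = list(min_div = 3, min_improve = 2, step = 10L),
    paths = list(outdir = "seedrecon_out")
  ), class = "seedrecon_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults section by section;
#' unknown keys are rejected by [validate_config()].
#'
#' @param path YAML file.
#' @return `seedrecon_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  # unknown top-level/nested keys are caught by validate_config
  attr(cfg, "user_keys") <- lapply(user, names)
  cfg
}

#' Validate a pipeline configuration
#'
#' Pure check: returns a character vector of violations (empty when the
#' configuration is valid). Unknown keys, out-of-range thresholds and
#' inconsistent stage parameters are reported with the offending field name.
#'
#' @param config A `seedrecon_config` list, or a path to a YAML file.
#' @return Character vector of violations; `character(0)` means ok.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  v <- character(0)
  ref <- default_config()
  bad_top <- setdiff(names(config), names(ref))
  if (length(bad_top) > 0) v <- c(v, paste0("unknown key: ", bad_top))
  for (nm in intersect(names(config), names(ref))) {
    if (is.list(ref[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(ref[[nm]]))
      if (length(bad) > 0) v <- c(v, paste0("unknown key: ", nm, ".", bad))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$rng_seed) && length(config$rng_seed) == 1,
      "rng_seed must be a single integer")
  r <- config$recruit
  chk(r$min_identity >= 90 && r$min_identity <= 100,
      "recruit.min_identity must be in [90, 100]")
  chk(r$max_matches >= 1 && r$max_matches <= 10,
      "recruit.max_matches must be in [1, 10]")
  chk(r$min_aln_len > 0, "recruit.min_aln_len must be positive")
  chk(r$end_tol >= 0 && r$read_cover_tol >= 0,
      "recruit.end_tol / read_cover_tol must be >= 0")
  s <- config$seeds
  chk(s$identity > 0.5 && s$identity <= 1,
      "seeds.identity must be in (0.5, 1]")
  chk(s$n_samples >= 1, "seeds.n_samples must be >= 1")
  chk(s$top_k >= 1, "seeds.top_k must be >= 1")
  a <- config$assemble
  chk(a$k >= 15, "assemble.k must be >= 15")
  chk(a$min_cov >= 1, "assemble.min_cov must be >= 1")
  chk(a$min_report_len > 0, "assemble.min_report_len must be positive")
  sim <- config$simulate
  if (isTRUE(sim$enabled)) {
    chk(sim$n_genomes >= 2, "simulate.n_genomes must be >= 2")
    chk(sim$error_rate >= 0 && sim$error_rate <= 0.1,
        "simulate.error_rate must be in [0, 0.1]")
  }
  v
}

stage_seed <- function(rng_seed, offset, i = 0L) {
  as.integer((as.numeric(rng_seed) + offset * 1000 + i) %% .Machine$integer.max)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> seed calling -> recruitment -> assembly ->
#' evaluation (optional, simulated data only), with all outputs under
#' `config$paths$outdir` and a manifest recording parameters and output
#' checksums. Idempotent: rerunning with the same configuration reproduces
#' every output byte for byte.
#'
#' @param config `seedrecon_config` list or YAML path.
#' @return Invisibly, a list of class `seedrecon_run` with the manifest and
#'   the main result tables.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  v <- validate_config(config)
  if (length(v) > 0) {
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  counters <- list()
  note <- function(p) outputs <<- c(outputs, p)

  if (!isTRUE(config$simulate$enabled)) {
    stop("run_all currently orchestrates the simulated-data study; ",
         "for real data run the stage functions on your files",
         call. = FALSE)
  }

  ## --- simulate: community, truth, amplicons -------------------------------
  simcfg <- config$simulate
  sp <- sim_params(
    n_genomes = simcfg$n_genomes,
    n_samples_low = simcfg$n_samples_low,
    n_samples_high = simcfg$n_samples_high,
    n_shotgun_pairs = simcfg$n_shotgun_pairs,
    n_amplicon_reads = simcfg$n_amplicon_reads,
    error_rate = simcfg$error_rate,
    amplicon_error_rate = simcfg$amplicon_error_rate,
    insert_mean = simcfg$insert_mean, insert_sd = simcfg$insert_sd,
    rng_seed = stage_seed(config$rng_seed, 1))
  community <- simulate_community(sp)
  truth <- truth_tables(community, dir = file.path(outdir, "truth"))
  note(file.path(outdir, "truth", "truth_16s.fasta"))
  note(file.path(outdir, "truth", "abundances.tsv"))

  sample_ids <- unique(community$abundances$sample_id)
  amplicons <- purrr::map_dfr(seq_along(sample_ids), function(i) {
    set.seed(stage_seed(config$rng_seed, 2, i))
    simulate_amplicons(community, sample_ids[i])
  })

  ## --- seeds ---------------------------------------------------------------
  cl <- cluster_otus(amplicons, identity = config$seeds$identity)
  reference <- if (!is.null(config$seeds$reference)) {
    read_fasta(config$seeds$reference)
  } else NULL
  fk <- filter_known(cl$seeds, reference, identity = config$seeds$identity)
  n_sel <- min(config$seeds$n_samples, length(sample_ids))
  selected_samples <- select_samples(cl$otu_table, n_sel)
  seeds <- select_seeds(fk$novel, cl$otu_table, selected_samples,
                        K = config$seeds$top_k,
                        length_bounds = config$seeds$length_bounds)
  note(write_fasta(
    tibble::tibble(id = seeds$otu_id,
                   description = sprintf("rank=%d max_abund=%.4g",
                                         seeds$rank,
                                         seeds$max_rel_abundance),
                   sequence = seeds$sequence),
    file.path(outdir, "seeds.fasta")))
  note(write_otu_table(cl$otu_table, file.path(outdir, "otu_table.tsv")))
  note(write_tsv_plain(
    tibble::tibble(sample_id = selected_samples,
                   order = seq_along(selected_samples)),
    file.path(outdir, "selected_samples.tsv")))

  ## --- recruit: shotgun simulation + recruitment per selected sample ------
  abundance <- otu_rel_abundance(cl$otu_table)
  rp <- recruit_params(
    min_identity = config$recruit$min_identity,
    max_matches = config$recruit$max_matches,
    min_aln_len = config$recruit$min_aln_len,
    end_tol = config$recruit$end_tol,
    read_cover_tol = config$recruit$read_cover_tol,
    prefilter_k = config$recruit$prefilter_k)
  reads_dir <- file.path(outdir, "reads")
  dir.create(reads_dir, showWarnings = FALSE)
  all_pairs <- list(); all_hits <- list(); all_asg <- list()
  for (i in seq_along(selected_samples)) {
    sid <- selected_samples[i]
    set.seed(stage_seed(config$rng_seed, 3, match(sid, sample_ids)))
    pairs <- simulate_shotgun(community, sid)
    f1 <- file.path(reads_dir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(reads_dir, paste0(sid, "_R2.fastq"))
    write_fastq_pair(pairs, f1, f2)
    note(f1); note(f2)
    rec <- recruit_sample(pairs, seeds, abundance, rp)
    all_pairs[[sid]] <- pairs
    all_hits[[sid]] <- rec$hits
    all_asg[[sid]] <- rec$assignments
    counters[[sid]] <- list(
      pairs_in = nrow(pairs),
      assigned = sum(rec$assignments$reason == "assigned"),
      no_hit = sum(rec$assignments$reason == "no_hit"),
      too_many_seeds = sum(rec$assignments$reason == "too_many_seeds"))
  }
  pairs_all <- dplyr::bind_rows(all_pairs)
  hits_all <- dplyr::bind_rows(all_hits)
  asg_all <- dplyr::bind_rows(all_asg)
  note(write_hits_table(hits_all, file.path(outdir, "hits.tsv")))
  note(write_tsv_plain(asg_all, file.path(outdir, "assignments.tsv")))
  bins <- bin_pairs(asg_all, pairs_all)
  binfiles <- write_bins(bins, file.path(outdir, "bins"))
  for (p in c(binfiles$r1, binfiles$r2)) note(p)
  no_reads <- setdiff(seeds$otu_id, bins$seed_id)
  note(write_tsv_plain(tibble::tibble(seed_id = no_reads),
                       file.path(outdir, "seeds_no_reads.tsv")))

  ## --- assemble ------------------------------------------------------------
  ap <- assembly_params(
    k = config$assemble$k, min_cov = config$assemble$min_cov,
    max_len = config$assemble$max_len,
    min_report_len = config$assemble$min_report_len,
    branch_ratio = config$assemble$branch_ratio,
    min_identity = config$assemble$min_identity,
    min_anchor_len = config$assemble$min_anchor_len)
  asm <- assemble_bins(bins, seeds, ap)
  lf <- length_filter(asm, config$assemble$min_report_len)
  ok <- asm[asm$status == "ok", , drop = FALSE]
  note(write_fasta(
    tibble::tibble(id = ok$seed_id,
                   description = sprintf("length=%d n_pairs=%d status=%s",
                                         ok$length, ok$n_pairs, ok$status),
                   sequence = ok$sequence),
    file.path(outdir, "contigs.fasta")))
  note(write_tsv_plain(
    asm[, setdiff(names(asm), "sequence")],
    file.path(outdir, "assembly_report.tsv")))
  pool <- tibble::tibble(id = lf$reported$seed_id,
                         sequence = lf$reported$sequence)
  chim <- if (nrow(pool) > 0) {
    chimera_check(pool, pool, min_div = config$chimera$min_div,
                  min_improve = config$chimera$min_improve,
                  step = config$chimera$step)
  } else {
    tibble::tibble(id = character(0), chimera = character(0))
  }
  note(write_tsv_plain(chim, file.path(outdir, "chimera.tsv")))

  ## --- evaluate ------------------------------------------------------------
  scores <- NULL; recon <- NULL
  if (isTRUE(config$evaluate$enabled)) {
    truth_map <- build_seed_truth(seeds, truth$truth_16s)
    scores <- score_recruitment(asg_all, truth_map, pairs_all)
    recon <- reconstruction_report(
      asm, truth$truth_16s,
      success_identity = config$evaluate$success_identity)
    note(write_tsv_plain(truth_map, file.path(outdir, "seed_truth_map.tsv")))
    note(write_tsv_plain(scores, file.path(outdir, "recruitment_scores.tsv")))
    note(write_tsv_plain(recon, file.path(outdir, "reconstruction.tsv")))
  }

  ## --- manifest ------------------------------------------------------------
  cfg_path <- file.path(outdir, "config.yaml")
  cfg_clean <- unclass(config)
  attr(cfg_clean, "user_keys") <- NULL
  cfg_clean$paths$outdir <- "."  # recorded relative to the output root
  yaml::write_yaml(cfg_clean, cfg_path)
  note(cfg_path)
  outputs <- sort(unique(outputs))
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    counters = counters,
    outputs = lapply(stats::setNames(outputs, sub(paste0("^", outdir, "/?"),
                                                  "", outputs)),
                     function(p) unname(tools::md5sum(p))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res <- list(manifest = manifest, manifest_path = manifest_path,
              seeds = seeds, assignments = asg_all, assembly = asm,
              chimera = chim, scores = scores, reconstruction = recon,
              outdir = outdir)
  class(res) <- "seedrecon_run"
  invisible(res)
}

#' @export
print.seedrecon_run <- function(x, ...) {
  cat("seedrecon run in", x$outdir, "\n")
  cat("  seeds:", nrow(x$seeds), "\n")
  cat("  pairs assigned:", sum(x$assignments$reason == "assigned"), "\n")
  cat("  contigs ok:", sum(x$assembly$status == "ok"), "\n")
  invisible(x)
}
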