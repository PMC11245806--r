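#' @importFrom rlang .data
#' @import tibble
NULL

# Normalize raw sequence text: uppercase, RNA U -> T, IUPAC ambiguity -> N.
# Errors on characters that are not nucleotide codes at all.
normalize_seq <- function(x, context = "sequence") {
  x <- unname(toupper(x))
  x <- chartr("U", "T", x)
  x <- gsub("[RYSWKMBDHV]", "N", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in ", context, " (record ",
         which(bad)[1], ")", call. = FALSE)
  }
  x
}

split_header <- function(nm) {
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  list(id = id, description = desc)
}

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased, `U` is mapped to `T` and IUPAC ambiguity codes
#' are collapsed to `N`. Gzipped files are read transparently.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `id`, `description`, `sequence`, in file
#'   order. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                    error = function(e) character(0))
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0) {
    return(tibble::tibble(id = character(0), description = character(0),
                          sequence = character(0)))
  }
  if (!startsWith(first[1], ">")) {
    all_lines <- readLines(path, warn = FALSE)
    bad <- which(nzchar(trimws(all_lines)) & !startsWith(all_lines, ">"))[1]
    stop("malformed FASTA: sequence line before header at line ", bad,
         " of ", path, call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  hd <- split_header(names(x))
  tibble::tibble(
    id = hd$id,
    description = hd$description,
    sequence = normalize_seq(as.character(x), context = path)
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  x <- Biostrings::BStringSet(seqs$sequence)
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  names(x) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

strip_mate_suffix <- function(id) sub("[/_.][12]$", "", id)

#' Read a pair of FASTQ files into a paired-read tibble
#'
#' Mate IDs must pair up after stripping a trailing `/1`,`/2` (or `_1`,`_2`,
#' `.1`,`.2`) suffix from the first header token. Quality strings are carried
#' through for writing but are never used in alignment or filtering. If the
#' headers carry simulator provenance tags, a `genome` (and `locus`) column is
#' filled from mate 1's header.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (optionally gzipped).
#' @param sample_id Sample label attached to every pair.
#' @return Tibble with columns `pair_id`, `sample_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, `desc1`, `desc2`, `genome`, `locus`.
#' @export
read_fastq_pair <- function(path1, path2, sample_id) {
  r1 <- Biostrings::readBStringSet(path1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readBStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    stop("mate file record counts differ: ", length(r1), " vs ", length(r2),
         call. = FALSE)
  }
  h1 <- split_header(names(r1)); h2 <- split_header(names(r2))
  p1 <- strip_mate_suffix(h1$id); p2 <- strip_mate_suffix(h2$id)
  bad <- which(p1 != p2)
  if (length(bad) > 0) {
    stop("unpairable read IDs at record ", bad[1], ": '", h1$id[bad[1]],
         "' vs '", h2$id[bad[1]], "'", call. = FALSE)
  }
  tibble::tibble(
    pair_id = p1,
    sample_id = sample_id,
    seq1 = normalize_seq(as.character(r1), context = path1),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    seq2 = normalize_seq(as.character(r2), context = path2),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    desc1 = h1$description,
    desc2 = h2$description,
    genome = parse_provenance(paste(h1$id, h1$description)),
    locus = parse_locus(paste(h1$id, h1$description))
  )
}

#' Write a paired-read tibble as two FASTQ files
#'
#' @param pairs Tibble as returned by [read_fastq_pair()] (columns `pair_id`,
#'   `seq1`, `qual1`, `seq2`, `qual2`, optionally `desc1`, `desc2`).
#' @param path1,path2 Output FASTQ paths for mates 1 and 2.
#' @param mate_suffix If `TRUE` (default), append `/1` and `/2` to IDs.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(pairs, path1, path2, mate_suffix = TRUE) {
  write_one <- function(seqs, quals, ids, descs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ifelse(nzchar(descs), paste(ids, descs), ids)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  d1 <- if ("desc1" %in% names(pairs)) pairs$desc1 else rep("", nrow(pairs))
  d2 <- if ("desc2" %in% names(pairs)) pairs$desc2 else rep("", nrow(pairs))
  sfx1 <- if (mate_suffix) "/1" else ""
  sfx2 <- if (mate_suffix) "/2" else ""
  write_one(pairs$seq1, pairs$qual1, paste0(pairs$pair_id, sfx1), d1, path1)
  write_one(pairs$seq2, pairs$qual2, paste0(pairs$pair_id, sfx2), d2, path2)
  invisible(c(path1, path2))
}

#' Extract the genome-of-origin tag from a simulated read header
#'
#' The simulator writes `genome=<ID> locus=<copy index>` into read
#' descriptions. Absence of a tag is a value (`NA`), not an error.
#'
#' @param header Character vector of full header lines (id + description).
#' @return Character vector of genome IDs, `NA` where no tag is present.
#' @examples
#' parse_provenance("r17 genome=G042")   # "G042"
#' parse_provenance("SRR123.5 5 length=150")  # NA
#' @export
parse_provenance <- function(header) {
  m <- stringr::str_match(header, "(?:^|\\s)genome=(\\S+)")
  m[, 2]
}

# 16S copy index companion tag; internal
parse_locus <- function(header) {
  m <- stringr::str_match(header, "(?:^|\\s)locus=(\\d+)")
  as.integer(m[, 2])
}

#' Read an OTU count table from TSV
#'
#' First column is the OTU ID, remaining columns are per-sample integer
#' counts.
#'
#' @param path TSV path.
#' @return Wide tibble: `otu_id` plus one integer column per sample.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("OTU table has no columns: ", path, call. = FALSE)
  names(df)[1] <- "otu_id"
  if (nrow(df) == 0) {
    out <- tibble::as_tibble(df)
    out[-1] <- lapply(out[-1], as.integer)
    return(out)
  }
  for (j in seq_along(df)[-1]) {
    bad <- which(!grepl("^[0-9]+$", df[[j]]))
    if (length(bad) > 0) {
      stop("invalid count '", df[[j]][bad[1]], "' at OTU '",
           df$otu_id[bad[1]], "', sample '", names(df)[j], "'",
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(df)
  out[-1] <- lapply(out[-1], as.integer)
  if (anyDuplicated(out$otu_id)) stop("duplicate OTU ids", call. = FALSE)
  out
}

#' Write an OTU count table to TSV
#'
#' @param otu_table Wide tibble (`otu_id` + per-sample counts).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otu_table, path) {
  utils::write.table(otu_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write alignment hits as a 12-column BLAST-style tabular file
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Internal 0-based half-open coordinates are converted
#' to 1-based inclusive; on the minus strand, sstart/send are swapped
#' (sstart > send), as blastn does. evalue is written as 0 and bitscore holds
#' the raw alignment score. qseqid is `<read_id>/<mate>`. Rows are ordered by
#' (read id, mate, seed id).
#'
#' @param hits Hit tibble as produced by [align_to_seeds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  if (nrow(hits) == 0) {
    file.create(path)
    return(invisible(path))
  }
  h <- dplyr::arrange(hits, .data$read_id, .data$mate, .data$seed_id)
  sstart <- ifelse(h$strand == "+", h$seed_start + 1L, h$seed_end)
  send <- ifelse(h$strand == "+", h$seed_end, h$seed_start + 1L)
  rows <- data.frame(
    qseqid = paste0(h$read_id, "/", h$mate),
    sseqid = h$seed_id,
    pident = sprintf("%.2f", h$identity),
    length = h$aln_len,
    mismatch = h$mismatch,
    gapopen = h$gapopen,
    qstart = h$read_start + 1L,
    qend = h$read_end,
    sstart = sstart,
    send = send,
    evalue = 0,
    bitscore = h$score
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column BLAST-style hit table back into a hit tibble
#'
#' Inverse of [write_hits_table()] on its canonical form.
#'
#' @param path Path to the tabular file.
#' @return Hit tibble (see [align_to_seeds()] for columns).
#' @export
read_hits_table <- function(path) {
  empty <- tibble::tibble(
    read_id = character(0), mate = integer(0), seed_id = character(0),
    identity = numeric(0), aln_len = integer(0), mismatch = integer(0),
    gapopen = integer(0), read_start = integer(0), read_end = integer(0),
    seed_start = integer(0), seed_end = integer(0), strand = character(0),
    score = integer(0))
  if (file.size(path) == 0) return(empty)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  strand <- ifelse(df$sstart <= df$send, "+", "-")
  tibble::tibble(
    read_id = sub("/[12]$", "", df$qseqid),
    mate = as.integer(sub("^.*/", "", df$qseqid)),
    seed_id = df$sseqid,
    identity = as.numeric(df$pident),
    aln_len = as.integer(df$length),
    mismatch = as.integer(df$mismatch),
    gapopen = as.integer(df$gapopen),
    read_start = as.integer(df$qstart) - 1L,
    read_end = as.integer(df$qend),
    seed_start = as.integer(ifelse(strand == "+", df$sstart, df$send)) - 1L,
    seed_end = as.integer(ifelse(strand == "+", df$send, df$sstart)),
    strand = strand,
    score = as.integer(df$bitscore)
  )
}
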