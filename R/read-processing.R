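#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings' FASTQ support returning/consuming the
#' tidy read table used throughout the preprocessing stage.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a tibble with columns `read_id`,
#'   `sequence` and `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read FASTQ file: %s", path))
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(seqs),
    quality = as.character(S4Vectors::mcols(seqs)$qualities)
  )
}

#' @rdname read_fastq
#' @param reads A read tibble with `read_id`, `sequence` and (optionally)
#'   `quality` columns.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(
    ss, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

# Score every admissible 3' occurrence of the adapter in one read and
# return the trim point (0 when no occurrence qualifies). The best
# occurrence has the fewest mismatches per aligned base; ties go to the
# leftmost occurrence. Trailing partial occurrences (adapter running off
# the 3' end) are allowed down to `min_overlap` aligned bases.
best_adapter_cut <- function(seq_ints, adapter_ints, max_error_rate,
                             min_overlap) {
  L <- length(seq_ints)
  m <- length(adapter_ints)
  best_i <- 0L
  best_score <- Inf
  for (i in seq_len(L)) {
    l <- min(m, L - i + 1L)
    if (l < min_overlap) break
    mm <- sum(seq_ints[i:(i + l - 1L)] != adapter_ints[seq_len(l)])
    score <- mm / l
    if (score <= max_error_rate && score < best_score) {
      best_score <- score
      best_i <- i
    }
  }
  best_i
}

#' Remove a 3' adapter from raw reads
#'
#' Finds the best 3' adapter occurrence in each read (fewest mismatches per
#' aligned base, ties resolved leftmost) with at least `min_overlap`
#' matched bases and an error rate at most `max_error_rate`, and removes it
#' together with everything 3' of it. Reads without a qualifying occurrence
#' are flagged `adapter_found = FALSE` and left untouched; downstream
#' length filtering treats them as ineligible, mirroring the rule that only
#' reads *with* an adapter enter the analysis.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param adapter 3' adapter sequence (ACGT only).
#' @param max_error_rate Maximum mismatches per aligned base (default 0.1).
#' @param min_overlap Minimum aligned bases for a trailing occurrence
#'   (default 3).
#' @return The read tibble with trimmed `sequence`/`quality` and a logical
#'   `adapter_found` column.
#' @export
trim_adapters <- function(reads, adapter, max_error_rate = 0.1,
                          min_overlap = 3L) {
  if (!is.character(adapter) || length(adapter) != 1 || !nzchar(adapter) ||
      grepl("[^ACGT]", adapter)) {
    abort("`adapter` must be a non-empty string over A/C/G/T")
  }
  check_fraction(max_error_rate, "max_error_rate", closed_left = TRUE)
  a_ints <- utf8ToInt(adapter)
  cuts <- vapply(reads$sequence, function(s) {
    best_adapter_cut(utf8ToInt(s), a_ints, max_error_rate, min_overlap)
  }, integer(1), USE.NAMES = FALSE)
  found <- cuts > 0L
  out <- reads
  out$sequence <- ifelse(found, substr(reads$sequence, 1L, cuts - 1L),
                         reads$sequence)
  if ("quality" %in% names(out)) {
    out$quality <- ifelse(found, substr(reads$quality, 1L, cuts - 1L),
                          reads$quality)
  }
  out$adapter_found <- found
  out
}

#' Retain reads within a length window
#'
#' Keeps reads whose (trimmed) length lies in `[min_len, max_len]` — the
#' default 17-35 nt window of the small-RNA analysis; the boundaries are
#' inclusive. Only reads in which an adapter was found are eligible; if the
#' input lacks an `adapter_found` column (pre-trimmed data) all reads are
#' eligible.
#'
#' @param reads Read tibble, optionally with an `adapter_found` column.
#' @param min_len,max_len Inclusive length window (defaults 17 and 35).
#' @return A list with `reads` (the retained tibble) and `summary`, a
#'   one-row tibble counting `retained`, `too_short`, `too_long` and
#'   `no_adapter` reads.
#' @export
filter_read_lengths <- function(reads, min_len = 17L, max_len = 35L) {
  if (min_len > max_len) {
    abort("`min_len` must not exceed `max_len`")
  }
  eligible <- reads$adapter_found %||% rep(TRUE, nrow(reads))
  len <- nchar(reads$sequence)
  keep <- eligible & len >= min_len & len <= max_len
  summary <- tibble::tibble(
    retained = sum(keep),
    too_short = sum(eligible & len < min_len),
    too_long = sum(eligible & len > max_len),
    no_adapter = sum(!eligible)
  )
  list(reads = reads[keep, , drop = FALSE], summary = summary)
}

#' Ingest aligned reads from a SAM/BAM file
#'
#' Expects single-end alignments with at most one reported alignment per
#' read (best-stratum reporting). Unmapped records are excluded and
#' counted; reverse-strand alignments map to strand `-`. SAM's 1-based
#' positions are converted to the internal 0-based half-open convention,
#' and the aligned reference span is taken from the CIGAR string. As a
#' defensive re-check, reads whose sequence length falls outside
#' `[min_len, max_len]` are excluded and counted.
#'
#' Note the returned `sequence` is reference-oriented, as stored in
#' SAM/BAM; use [oriented_sequences()] to recover the biological read
#' orientation (5' end first).
#'
#' @param path SAM or BAM file path (SAM text is converted on the fly).
#' @param min_len,max_len Inclusive length window (defaults 17 and 35).
#' @return A tibble with `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `sequence`, `length`; drop counts are attached as attribute
#'   `dropped` (a one-row tibble).
#' @export
read_sam <- function(path, min_len = 17L, max_len = 35L) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read alignment file: %s", path))
  }
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    header <- readLines(path, n = 200L, warn = FALSE)
    if (!any(startsWith(header, "@SQ"))) {
      abort(sprintf("SAM file %s lacks an @SQ sequence dictionary in its header",
                    path))
    }
    bam <- suppressMessages(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  secondary <- bitwAnd(rec$flag, 256L) > 0L | bitwAnd(rec$flag, 2048L) > 0L
  keep <- !unmapped & !secondary
  qname <- rec$qname[keep]
  if (anyDuplicated(qname)) {
    abort(sprintf(
      "multiple primary alignments found for read(s): %s",
      paste(head(unique(qname[duplicated(qname)]), 3), collapse = ", ")))
  }
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  out <- tibble::tibble(
    read_id = qname,
    chrom = as.character(rec$rname[keep]),
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + span,
    strand = as.character(rec$strand[keep]),
    sequence = as.character(rec$seq[keep]),
    length = nchar(as.character(rec$seq[keep]))
  )
  in_range <- out$length >= min_len & out$length <= max_len
  dropped <- tibble::tibble(unmapped = sum(unmapped),
                            out_of_range = sum(!in_range))
  structure(out[in_range, , drop = FALSE], dropped = dropped)
}

#' Write aligned reads to a SAM file
#'
#' Emits a minimal single-end SAM file (header `@HD`/`@SQ` plus one record
#' per read) consistent with [read_sam()]: positions convert back to
#' 1-based, `-`-strand reads get FLAG 16, and the CIGAR is the aligned
#' span as a single match run. Round-tripping through [read_sam()] is the
#' identity on `(read_id, chrom, start, end, strand)`.
#'
#' @param reads Aligned-read tibble (see [read_sam()]); `sequence` must be
#'   reference-oriented.
#' @param path Output path.
#' @param genome Optional named vector of chromosome lengths for the `@SQ`
#'   lines; defaults to the maximum end per chromosome.
#' @export
write_sam <- function(reads, path, genome = NULL) {
  if (is.null(genome)) {
    genome <- vapply(split(reads$end, reads$chrom), max, numeric(1))
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome))
  )
  span <- reads$end - reads$start
  records <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
    reads$read_id,
    ifelse(reads$strand == "-", 16L, 0L),
    reads$chrom,
    reads$start + 1L,
    span,
    reads$sequence,
    strrep("I", nchar(reads$sequence))
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Recover biological read orientation
#'
#' SAM stores sequences in reference orientation; for `-`-strand
#' alignments the biological read is the reverse complement, so that
#' position 1 is the 5' end. Used by the 5'-base composition statistics.
#'
#' @param reads Aligned-read tibble with `sequence` and `strand` columns.
#' @return Character vector of read-oriented sequences.
#' @export
oriented_sequences <- function(reads) {
  out <- reads$sequence
  neg <- reads$strand == "-"
  if (any(neg)) {
    out[neg] <- reverse_complement(out[neg])
  }
  out
}
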