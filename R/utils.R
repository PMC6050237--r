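# Internal helpers shared across modules.

# Canonical tier order of the annotation cascade.
TIER_ORDER <- c("small_rna", "rrna", "other_rna")

# Column order of a feature table (internal coordinates are 0-based
# half-open; GTF input is converted on read, BED is taken as-is).
FEATURE_COLS <- c("chrom", "start", "end", "strand", "gene_id", "gene_name",
                  "biotype", "source")

empty_features <- function() {
  tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), gene_id = character(), gene_name = character(),
    biotype = character(), source = character()
  )
}

validate_features <- function(features, arg = "features") {
  missing_cols <- setdiff(setdiff(FEATURE_COLS, "source"), names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing required columns: %s",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  if (any(features$start >= features$end)) {
    abort(sprintf("`%s` contains features with start >= end", arg))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    abort(sprintf("`%s` contains strands other than '+'/'-'", arg))
  }
  invisible(features)
}

# Build a stranded GRanges from a 0-based half-open interval table.
# `seqlevels` lets callers put query and subject on a common set of
# chromosome names so overlap queries do not warn about mismatches.
intervals_to_granges <- function(df, seqlevels = NULL) {
  seqlevels <- seqlevels %||% unique(as.character(df$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

# Stranded overlap hits between two interval tables; returns a tibble of
# (query row index, subject row index, overlap width in bases).
interval_hits <- function(query, subject, min_overlap = 1L) {
  lev <- union(unique(as.character(query$chrom)),
               unique(as.character(subject$chrom)))
  qg <- intervals_to_granges(query, seqlevels = lev)
  sg <- intervals_to_granges(subject, seqlevels = lev)
  hits <- GenomicRanges::findOverlaps(qg, sg, minoverlap = min_overlap)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  width <- pmin(query$end[qh], subject$end[sh]) -
    pmax(query$start[qh], subject$start[sh])
  tibble::tibble(query = qh, subject = sh, overlap = width)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_fraction <- function(x, arg, closed_left = FALSE) {
  lo_ok <- if (closed_left) x >= 0 else x > 0
  if (!is.numeric(x) || length(x) != 1 || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a fraction in %s0, 1]",
                  arg, if (closed_left) "[" else "("))
  }
  invisible(x)
}
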