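#' Read genomic features from a GTF/GFF2 file
#'
#' Parses a GTF (GFF2 dialect) annotation file into a feature table. GTF
#' coordinates are 1-based inclusive; they are converted to the package's
#' internal 0-based half-open convention on read. Records without a `gene_id`
#' attribute or without a definite strand (`+`/`-`) are rejected and the
#' number of rejected records is reported.
#'
#' @param path Path to a GTF file.
#' @param biotype_attr Name of the attribute holding the gene biotype
#'   (default `"gene_biotype"`).
#' @param source Provenance tag stored in the `source` column; defaults to
#'   the file name.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_name`, `biotype`, `source`. The number of rejected
#'   records is attached as attribute `n_rejected`.
#' @export
read_gtf <- function(path, biotype_attr = "gene_biotype",
                     source = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read GTF file: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body) == 0) {
    warn(sprintf("GTF file %s contains no feature lines", path))
    return(structure(empty_features(), n_rejected = 0L))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- body[which(nf < 9)[1]]
    abort(sprintf(
      "malformed GTF line %d in %s: expected 9 tab-separated fields, found %d",
      bad, path, nf[which(nf < 9)[1]]))
  }
  starts <- vapply(fields, `[`, "", 4L)
  ends <- vapply(fields, `[`, "", 5L)
  non_num <- !grepl("^[0-9]+$", starts) | !grepl("^[0-9]+$", ends)
  if (any(non_num)) {
    abort(sprintf("malformed GTF line %d in %s: non-numeric coordinates",
                  body[which(non_num)[1]], path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else
    rep(NA_character_, length(gr))
  gene_name <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else
    rep(NA_character_, length(gr))
  biotype <- if (biotype_attr %in% names(mc)) as.character(mc[[biotype_attr]]) else
    rep(NA_character_, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  keep <- strand %in% c("+", "-") & !is.na(gene_id) & nzchar(gene_id)
  n_rejected <- sum(!keep)
  if (n_rejected > 0) {
    inform(sprintf("read_gtf: rejected %d record(s) lacking strand or gene_id",
                   n_rejected))
  }
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = BiocGenerics::start(gr)[keep] - 1L,
    end = BiocGenerics::end(gr)[keep],
    strand = strand[keep],
    gene_id = gene_id[keep],
    gene_name = gene_name[keep],
    biotype = biotype[keep],
    source = source
  )
  structure(out, n_rejected = n_rejected)
}

#' Read genomic features from a BED6 file
#'
#' BED coordinates are already 0-based half-open and are kept as-is. The
#' `name` column becomes `gene_id` (and `gene_name`), and every feature
#' receives the supplied biotype. Stranded annotation requires a definite
#' strand, so entries with strand `.` are an error.
#'
#' @param path Path to a BED file with at least 6 columns.
#' @param biotype Biotype label applied to every feature (e.g. `"tRNA"`).
#' @param source Provenance tag; defaults to the file name.
#' @return A feature tibble (see [read_gtf()]).
#' @export
read_bed <- function(path, biotype, source = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read BED file: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) {
    warn(sprintf("BED file %s contains no feature lines", path))
    return(empty_features())
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    i <- which(nf < 6)[1]
    abort(sprintf("BED line %d in %s has %d column(s); at least 6 required",
                  body[i], path, nf[i]))
  }
  strand <- vapply(fields, `[`, "", 6L)
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    i <- which(bad_strand)[1]
    abort(sprintf(
      "BED line %d in %s has strand '%s'; stranded annotation requires '+' or '-'",
      body[i], path, strand[i]))
  }
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = as.character(gr$name),
    gene_name = as.character(gr$name),
    biotype = biotype,
    source = source
  )
}

#' Drop candidate features that reciprocally overlap a reference set
#'
#' Used when merging rRNA annotation sources: a candidate entry is removed
#' when some reference entry on the same chromosome and strand overlaps it
#' by at least `min_fraction` of the candidate length *and* at least
#' `min_fraction` of the reference length (BEDTools `-f -r` semantics).
#' Candidates failing either arm of the reciprocal test are retained, so a
#' short reference fully inside a long candidate does not remove it.
#'
#' @param candidates,reference Feature tibbles (see [read_gtf()]).
#' @param min_fraction Reciprocal overlap fraction in (0, 1]; default 0.5.
#' @return The retained subset of `candidates`, input order preserved.
#' @export
reciprocal_overlap_filter <- function(candidates, reference,
                                      min_fraction = 0.5) {
  check_fraction(min_fraction, "min_fraction")
  validate_features(candidates, "candidates")
  validate_features(reference, "reference")
  if (nrow(candidates) == 0 || nrow(reference) == 0) {
    return(candidates)
  }
  hits <- interval_hits(candidates, reference)
  cand_len <- candidates$end[hits$query] - candidates$start[hits$query]
  ref_len <- reference$end[hits$subject] - reference$start[hits$subject]
  removed <- unique(hits$query[
    hits$overlap >= min_fraction * cand_len &
      hits$overlap >= min_fraction * ref_len
  ])
  candidates[setdiff(seq_len(nrow(candidates)), removed), , drop = FALSE]
}

#' Default biotype vocabulary of the three annotation tiers
#'
#' The 'small RNA' tier holds miRNA, piRNA, snRNA and snoRNA; the 'rRNA'
#' tier holds large- and small-subunit ribosomal RNA and mitochondrial
#' rRNA; everything else (tRNA, mitochondrial tRNA, protein coding, lncRNA,
#' miscellaneous RNA, processed transcripts, pseudogenes, scRNA) is
#' 'other RNA'.
#'
#' @return A named list mapping tier name to its biotype vector.
#' @export
default_tier_vocabulary <- function() {
  list(
    small_rna = c("miRNA", "piRNA", "snRNA", "snoRNA"),
    rrna = c("rRNA_LSU", "rRNA_SSU", "Mt_rRNA"),
    other_rna = c("tRNA", "Mt_tRNA", "protein_coding", "lncRNA", "misc_RNA",
                  "processed_transcript", "pseudogene", "scRNA")
  )
}

#' Build and validate the biotype-to-tier mapping
#'
#' @param spec Either `NULL` (default vocabulary), a named list mapping
#'   tier name to a character vector of biotypes, or a named character
#'   vector mapping biotype to tier. The mapping must cover the full
#'   default vocabulary; additional biotypes extend it.
#' @return A named character vector `biotype -> tier` with class
#'   `tier_config`.
#' @export
build_tier_config <- function(spec = NULL) {
  if (is.null(spec)) {
    spec <- default_tier_vocabulary()
  }
  if (is.list(spec)) {
    bad_tier <- setdiff(names(spec), TIER_ORDER)
    if (length(bad_tier) > 0) {
      abort(sprintf("unknown tier name(s): %s; tiers are %s",
                    paste(bad_tier, collapse = ", "),
                    paste(TIER_ORDER, collapse = ", ")))
    }
    map <- setNames(rep(names(spec), lengths(spec)), unlist(spec))
  } else if (is.character(spec) && !is.null(names(spec))) {
    bad_tier <- setdiff(unique(spec), TIER_ORDER)
    if (length(bad_tier) > 0) {
      abort(sprintf("unknown tier name(s): %s", paste(bad_tier, collapse = ", ")))
    }
    map <- spec
  } else {
    abort("`spec` must be NULL, a named list tier -> biotypes, or a named character vector biotype -> tier")
  }
  dup <- unique(names(map)[duplicated(names(map))])
  # a biotype listed twice under the same tier is harmless; two tiers is not
  if (length(dup) > 0) {
    conflict <- dup[vapply(dup, function(b)
      length(unique(map[names(map) == b])) > 1, logical(1))]
    if (length(conflict) > 0) {
      abort(sprintf("biotype(s) mapped to more than one tier: %s",
                    paste(conflict, collapse = ", ")))
    }
    map <- map[!duplicated(names(map))]
  }
  missing_bt <- setdiff(unlist(default_tier_vocabulary()), names(map))
  if (length(missing_bt) > 0) {
    abort(sprintf("tier config must cover the default vocabulary; missing: %s",
                  paste(missing_bt, collapse = ", ")))
  }
  structure(map, class = c("tier_config", "character"))
}

#' Build the three-tier annotation database
#'
#' Assigns each feature to its tier via the biotype-to-tier config,
#' deduplicates features with identical `(chrom, start, end, strand,
#' gene_id)` (identical intervals belonging to *different* genes both
#' survive and later produce ambiguous read assignments), and builds
#' per-tier stranded interval indexes for fast overlap queries.
#'
#' @param features Feature tibble (from [read_gtf()], [read_bed()] or the
#'   synthetic generator). rRNA sources should have been merged with
#'   [reciprocal_overlap_filter()] beforehand.
#' @param config A `tier_config` from [build_tier_config()].
#' @return A `tiered_annotation` object: the deduplicated feature table
#'   (with a `tier` column), the config and the per-tier interval indexes.
#' @export
build_tiered_annotation <- function(features, config = build_tier_config()) {
  validate_features(features)
  if (!"source" %in% names(features)) {
    features$source <- NA_character_
  }
  unknown <- setdiff(unique(features$biotype), names(config))
  if (length(unknown) > 0) {
    abort(sprintf("feature biotype(s) absent from tier config: %s",
                  paste(unknown, collapse = ", ")))
  }
  key <- paste(features$chrom, features$start, features$end,
               features$strand, features$gene_id, sep = "\r")
  dup <- duplicated(key)
  n_duplicates <- sum(dup)
  if (n_duplicates > 0) {
    inform(sprintf("build_tiered_annotation: removed %d duplicate feature(s)",
                   n_duplicates))
  }
  features <- features[!dup, , drop = FALSE]
  features$tier <- unname(config[features$biotype])
  features <- dplyr::arrange(
    features,
    match(.data$tier, TIER_ORDER), .data$biotype, .data$gene_id,
    .data$chrom, .data$start, .data$end, .data$strand
  )
  chroms <- sort(unique(features$chrom))
  index <- lapply(setNames(TIER_ORDER, TIER_ORDER), function(t) {
    rows <- which(features$tier == t)
    gr <- intervals_to_granges(features[rows, , drop = FALSE],
                               seqlevels = chroms)
    S4Vectors::mcols(gr)$row <- rows
    gr
  })
  structure(
    list(features = tibble::as_tibble(features), config = config,
         index = index, chroms = chroms, n_duplicates = n_duplicates),
    class = "tiered_annotation"
  )
}

#' @export
print.tiered_annotation <- function(x, ...) {
  cat("Tiered small-RNA annotation\n")
  for (t in TIER_ORDER) {
    n <- sum(x$features$tier == t)
    bts <- sort(unique(x$features$biotype[x$features$tier == t]))
    cat(sprintf("  %-9s %6d features (%s)\n", t, n,
                paste(bts, collapse = ", ")))
  }
  cat(sprintf("  chromosomes: %s\n", paste(x$chroms, collapse = ", ")))
  invisible(x)
}

# Stranded overlap query against one tier of the database. Returns a tibble
# of (query row in `reads`, feature row in annotation$features, overlap).
tier_hits <- function(annotation, reads, tier, min_overlap = 1L) {
  gr <- annotation$index[[tier]]
  if (length(gr) == 0 || nrow(reads) == 0) {
    return(tibble::tibble(query = integer(), feature = integer(),
                          overlap = integer()))
  }
  lev <- union(annotation$chroms, unique(as.character(reads$chrom)))
  rg <- intervals_to_granges(reads, seqlevels = lev)
  GenomeInfoDb::seqlevels(gr) <- lev
  hits <- GenomicRanges::findOverlaps(rg, gr, minoverlap = min_overlap)
  qh <- S4Vectors::queryHits(hits)
  fr <- S4Vectors::mcols(gr)$row[S4Vectors::subjectHits(hits)]
  ov <- pmin(reads$end[qh], annotation$features$end[fr]) -
    pmax(reads$start[qh], annotation$features$start[fr])
  tibble::tibble(query = qh, feature = fr, overlap = ov)
}

#' Query features overlapping an interval
#'
#' @param annotation A `tiered_annotation`.
#' @param chrom,start,end,strand The stranded query interval (0-based
#'   half-open).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return The rows of the feature table overlapping the query.
#' @export
query_annotation <- function(annotation, chrom, start, end, strand,
                             min_overlap = 1L) {
  q <- tibble::tibble(chrom = chrom, start = start, end = end, strand = strand)
  rows <- unlist(lapply(TIER_ORDER, function(t)
    tier_hits(annotation, q, t, min_overlap)$feature))
  annotation$features[sort(rows), , drop = FALSE]
}

#' Serialize / restore an annotation database
#'
#' The database round-trips losslessly through a tab-separated feature dump
#' (`features.tsv`) plus a sidecar tier-config file (`tier_config.tsv`).
#'
#' @param annotation A `tiered_annotation`.
#' @param dir Directory to write to (created if needed).
#' @return `write_annotation_db()` returns the directory invisibly;
#'   `read_annotation_db()` returns the restored `tiered_annotation`.
#' @export
write_annotation_db <- function(annotation, dir) {
  stopifnot(inherits(annotation, "tiered_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(annotation$features, file.path(dir, "features.tsv"),
                   na = "")
  cfg <- tibble::tibble(biotype = names(annotation$config),
                        tier = unname(annotation$config))
  readr::write_tsv(cfg, file.path(dir, "tier_config.tsv"))
  invisible(dir)
}

#' @rdname write_annotation_db
#' @export
read_annotation_db <- function(dir) {
  fpath <- file.path(dir, "features.tsv")
  cpath <- file.path(dir, "tier_config.tsv")
  if (!file.exists(fpath) || !file.exists(cpath)) {
    abort(sprintf("annotation database not found under %s", dir))
  }
  features <- readr::read_tsv(
    fpath,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), strand = readr::col_character(),
      gene_id = readr::col_character(), gene_name = readr::col_character(),
      biotype = readr::col_character(), tier = readr::col_character(),
      source = readr::col_character()
    ), na = ""
  )
  cfg <- readr::read_tsv(cpath, col_types = readr::cols(
    biotype = readr::col_character(), tier = readr::col_character()
  ))
  config <- build_tier_config(setNames(cfg$tier, cfg$biotype))
  build_tiered_annotation(
    dplyr::select(features, -"tier"), config
  )
}
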