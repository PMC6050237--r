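#' Assign aligned reads through the three-tier annotation cascade
#'
#' Tiers are visited in strict priority order ('small RNA', then 'rRNA',
#' then 'other RNA'). At the first tier where at least one feature overlaps
#' the read interval on the read's strand by at least `min_overlap` bases,
#' the read stops: if all overlapping features share a single `gene_id` the
#' read is `assigned` to that gene (HTSeq union-mode semantics); if two or
#' more distinct genes overlap it is `ambiguous` at that tier and does
#' *not* continue to later tiers — only reads with no found feature pass
#' down the cascade. Reads overlapping nothing in any tier are
#' `unassigned`.
#'
#' @param reads Aligned-read tibble (see [read_sam()]).
#' @param annotation A `tiered_annotation` from [build_tiered_annotation()].
#' @param min_overlap Minimum overlap in bases (default 1, i.e. any
#'   overlap).
#' @return The read tibble with columns `status`
#'   (`assigned`/`ambiguous`/`unassigned`), `tier`, `biotype`, `gene_id`
#'   and a list-column `candidate_gene_ids`. The number of reads on
#'   chromosomes absent from the annotation is attached as attribute
#'   `n_unknown_chrom`.
#' @export
assign_reads <- function(reads, annotation, min_overlap = 1L) {
  stopifnot(inherits(annotation, "tiered_annotation"))
  n <- nrow(reads)
  status <- rep("unassigned", n)
  tier <- rep(NA_character_, n)
  biotype <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  candidates <- rep(list(character()), n)
  remaining <- seq_len(n)
  for (t in TIER_ORDER) {
    if (length(remaining) == 0) break
    hits <- tier_hits(annotation, reads[remaining, , drop = FALSE], t,
                      min_overlap = min_overlap)
    if (nrow(hits) == 0) next
    hit_genes <- tibble::tibble(
      query = hits$query,
      gene_id = annotation$features$gene_id[hits$feature],
      biotype = annotation$features$biotype[hits$feature]
    )
    hg <- hit_genes[order(hit_genes$query, hit_genes$gene_id,
                          hit_genes$biotype), , drop = FALSE]
    # uniqueness is per gene id (union-mode semantics): a gene annotated
    # under two biotypes at one locus still counts as a single gene
    hg <- hg[!duplicated(hg[c("query", "gene_id")]), , drop = FALSE]
    qf <- factor(hg$query, levels = unique(hg$query))
    genes_by_read <- split(hg$gene_id, qf)
    n_genes <- lengths(genes_by_read)
    qidx <- as.integer(names(genes_by_read))
    gi <- remaining[qidx]
    tier[gi] <- t
    candidates[gi] <- unname(genes_by_read)
    single <- n_genes == 1
    status[gi[single]] <- "assigned"
    status[gi[!single]] <- "ambiguous"
    gene_id[gi[single]] <- unlist(genes_by_read[single], use.names = FALSE)
    first_bt <- hg$biotype[!duplicated(hg$query)]
    biotype[gi[single]] <- first_bt[single]
    remaining <- remaining[-qidx]
  }
  out <- reads
  out$status <- status
  out$tier <- tier
  out$biotype <- biotype
  out$gene_id <- gene_id
  out$candidate_gene_ids <- candidates
  structure(out,
            n_unknown_chrom = sum(!reads$chrom %in% annotation$chroms &
                                    status == "unassigned"))
}

#' Tabulate read assignments into a gene-level count table
#'
#' @param assignments Output of [assign_reads()] for one sample.
#' @param sample Sample name; becomes the count column name.
#' @return A `count_table` object: `counts` (tibble keyed by
#'   `gene_id`/`biotype`/`tier` with one count column per sample, rows in
#'   deterministic tier/biotype/gene order), `ambiguous` (per-sample,
#'   per-tier tallies) and `unassigned` (per-sample tally).
#' @export
count_reads <- function(assignments, sample = "sample1") {
  assigned <- dplyr::filter(assignments, .data$status == "assigned")
  counts <- assigned |>
    dplyr::count(.data$gene_id, .data$biotype, .data$tier, name = "n") |>
    dplyr::arrange(match(.data$tier, TIER_ORDER), .data$biotype,
                   .data$gene_id) |>
    dplyr::rename(!!sample := "n")
  ambiguous <- assignments |>
    dplyr::filter(.data$status == "ambiguous") |>
    dplyr::count(.data$tier, name = "n")
  ambiguous <- tibble::tibble(
    sample = sample, tier = TIER_ORDER,
    n = vapply(TIER_ORDER, function(t) {
      i <- match(t, ambiguous$tier)
      if (is.na(i)) 0L else ambiguous$n[i]
    }, integer(1))
  )
  unassigned <- tibble::tibble(
    sample = sample,
    n = sum(assignments$status == "unassigned")
  )
  new_count_table(counts, ambiguous, unassigned)
}

new_count_table <- function(counts, ambiguous, unassigned) {
  structure(list(counts = counts, ambiguous = ambiguous,
                 unassigned = unassigned),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  samples <- count_table_samples(x)
  cat(sprintf("Gene-level count table: %d gene(s), %d sample(s)\n",
              nrow(x$counts), length(samples)))
  print(x$counts, n = 10)
  invisible(x)
}

count_table_samples <- function(table) {
  setdiff(names(table$counts), c("gene_id", "biotype", "tier"))
}

#' Merge single-sample count tables
#'
#' @param ... `count_table` objects with distinct sample names.
#' @return A multi-sample `count_table`; genes absent from a sample get 0.
#' @export
bind_count_tables <- function(...) {
  tables <- list(...)
  counts <- purrr::reduce(
    lapply(tables, `[[`, "counts"),
    function(a, b) dplyr::full_join(a, b, by = c("gene_id", "biotype", "tier"))
  )
  samples <- setdiff(names(counts), c("gene_id", "biotype", "tier"))
  counts <- counts |>
    dplyr::mutate(dplyr::across(dplyr::all_of(samples),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::arrange(match(.data$tier, TIER_ORDER), .data$biotype,
                   .data$gene_id)
  new_count_table(
    counts,
    dplyr::bind_rows(lapply(tables, `[[`, "ambiguous")),
    dplyr::bind_rows(lapply(tables, `[[`, "unassigned"))
  )
}

#' Pool tRNA read counts by isoacceptor
#'
#' tRNA counts originating from different genomic loci of the same
#' isoacceptor (identical amino acid and anticodon, e.g. every
#' `tRNA-Gly-GCC-<locus>` gene) are merged into a single row keyed
#' `tRNA-<AA>-<anticodon>`. Non-tRNA rows are untouched and total counts
#' are conserved. tRNA gene ids that do not match the pattern are left
#' unpooled with a warning.
#'
#' @param table A `count_table`.
#' @param pattern Regular expression with two capture groups (amino acid,
#'   anticodon) applied to tRNA gene ids.
#' @param biotypes Biotypes subject to pooling (default `"tRNA"`).
#' @return The pooled `count_table`.
#' @export
pool_trna_isoacceptors <- function(table,
                                   pattern = "^tRNA-([A-Za-z]+)-([A-Za-z]+)",
                                   biotypes = "tRNA") {
  stopifnot(inherits(table, "count_table"))
  counts <- table$counts
  is_trna <- counts$biotype %in% biotypes
  m <- stringr::str_match(counts$gene_id[is_trna], pattern)
  unmatched <- counts$gene_id[is_trna][is.na(m[, 1])]
  if (length(unmatched) > 0) {
    warn(sprintf("tRNA gene id(s) not matching the isoacceptor pattern left unpooled: %s",
                 paste(unique(unmatched), collapse = ", ")))
  }
  pooled_id <- counts$gene_id
  ok <- which(is_trna)[!is.na(m[, 1])]
  pooled_id[ok] <- sprintf("tRNA-%s-%s", m[!is.na(m[, 1]), 2],
                           m[!is.na(m[, 1]), 3])
  samples <- count_table_samples(table)
  counts$gene_id <- pooled_id
  counts <- counts |>
    dplyr::group_by(.data$gene_id, .data$biotype, .data$tier) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(samples), sum),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$tier, TIER_ORDER), .data$biotype,
                   .data$gene_id)
  new_count_table(counts, table$ambiguous, table$unassigned)
}

#' Count-threshold normalisation of miRNA/piRNA counts
#'
#' Genes of the chosen biotype with at least `min_count` reads are
#' normalised over the *total* number of reads of that biotype in the
#' sample (including reads of sub-threshold genes); sub-threshold genes are
#' omitted from the output. Fractions therefore sum to at most 1, with
#' equality exactly when no gene fell below the threshold.
#'
#' @param table A `count_table`.
#' @param biotype Biotype to normalise (typically `"miRNA"` or `"piRNA"`).
#' @param sample Sample name; defaults to the table's single sample.
#' @param min_count Minimum read count for a gene to be reported
#'   (default 3).
#' @return A tibble with `gene_id`, `count` and `fraction`, sorted by
#'   decreasing fraction then gene id.
#' @export
threshold_normalize <- function(table, biotype, sample = NULL,
                                min_count = 3L) {
  stopifnot(inherits(table, "count_table"))
  samples <- count_table_samples(table)
  sample <- sample %||% {
    if (length(samples) != 1) {
      abort("`sample` must be given for a multi-sample count table")
    }
    samples
  }
  if (!sample %in% samples) {
    abort(sprintf("sample '%s' not present in the count table", sample))
  }
  rows <- table$counts[table$counts$biotype == biotype, , drop = FALSE]
  total <- sum(rows[[sample]])
  if (total == 0) {
    warn(sprintf("no %s reads in sample '%s'; returning empty normalisation",
                 biotype, sample))
    return(tibble::tibble(gene_id = character(), count = integer(),
                          fraction = double()))
  }
  rows <- rows[rows[[sample]] >= min_count, , drop = FALSE]
  tibble::tibble(
    gene_id = rows$gene_id,
    count = rows[[sample]],
    fraction = rows[[sample]] / total
  ) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$gene_id)
}

#' Cross-biotype annotation ambiguity masked by the cascade
#'
#' Because the cascade stops at the first tier with a hit, a read assigned
#' to an early-tier biotype (e.g. piRNA) may silently also overlap a
#' later-tier biotype's locus (e.g. tRNA). For every read assigned to
#' `biotype_a`, all tiers are re-queried ignoring priority; the read is
#' cross-ambiguous if any `biotype_b` feature overlaps it on the same
#' strand. The returned fraction is over all annotated reads (assigned
#' plus ambiguous), a per-read definition.
#'
#' @param assignments Output of [assign_reads()].
#' @param annotation The `tiered_annotation` the assignments came from.
#' @param biotype_a Biotype the reads were assigned to (earlier tier).
#' @param biotype_b Potentially masked biotype (later tier).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return A one-row tibble with `n_cross`, `n_annotated` and `fraction`.
#' @export
cross_biotype_ambiguity <- function(assignments, annotation, biotype_a,
                                    biotype_b, min_overlap = 1L) {
  for (b in c(biotype_a, biotype_b)) {
    if (!b %in% names(annotation$config)) {
      abort(sprintf("unknown biotype '%s'", b))
    }
  }
  n_annotated <- sum(assignments$status %in% c("assigned", "ambiguous"))
  a_reads <- dplyr::filter(assignments, .data$status == "assigned",
                           .data$biotype == biotype_a)
  if (nrow(a_reads) == 0 || n_annotated == 0) {
    return(tibble::tibble(n_cross = 0L, n_annotated = n_annotated,
                          fraction = if (n_annotated == 0) NA_real_ else 0))
  }
  b_features <- annotation$features[annotation$features$biotype == biotype_b, ,
                                    drop = FALSE]
  if (nrow(b_features) == 0) {
    return(tibble::tibble(n_cross = 0L, n_annotated = n_annotated,
                          fraction = 0))
  }
  hits <- interval_hits(a_reads, b_features, min_overlap = min_overlap)
  n_cross <- length(unique(hits$query))
  tibble::tibble(n_cross = n_cross, n_annotated = n_annotated,
                 fraction = n_cross / n_annotated)
}
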