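#' Run the full small-RNA profiling pipeline on one sample
#'
#' Convenience wrapper chaining the cascade and the composition
#' statistics: assign reads through the tier cascade, tabulate gene-level
#' counts, pool tRNA isoacceptors, threshold-normalise miRNA and piRNA
#' counts (read count >= `min_count` over the biotype total) and compute
#' category/biotype fractions plus length and 5'-base summaries.
#'
#' @param reads Aligned-read tibble (from [read_sam()] or
#'   [generate_reads()]).
#' @param annotation A `tiered_annotation`.
#' @param sample Sample name.
#' @param min_count Normalisation threshold (default 3).
#' @param denominator Passed to [category_fractions()].
#' @return A `small_rna_profile` list: `assignments`, `counts` (pooled
#'   `count_table`), `composition`, `mirna_norm`, `pirna_norm`,
#'   `length_dist`, `pirna_bases`.
#' @export
profile_small_rna <- function(reads, annotation, sample = "sample1",
                              min_count = 3L,
                              denominator = "assigned_only") {
  assignments <- assign_reads(reads, annotation)
  counts <- count_reads(assignments, sample = sample) |>
    pool_trna_isoacceptors()
  structure(
    list(
      sample = sample,
      assignments = assignments,
      counts = counts,
      composition = category_fractions(counts, sample = sample,
                                       denominator = denominator),
      mirna_norm = threshold_normalize(counts, "miRNA", sample = sample,
                                       min_count = min_count),
      pirna_norm = threshold_normalize(counts, "piRNA", sample = sample,
                                       min_count = min_count),
      length_dist = length_distribution(assignments),
      pirna_bases = first_base_composition(assignments, biotype = "piRNA")
    ),
    class = "small_rna_profile"
  )
}

#' @export
print.small_rna_profile <- function(x, ...) {
  cat(sprintf("Small-RNA profile of sample '%s'\n", x$sample))
  print(x$composition$category)
  invisible(x)
}

#' Write the pipeline outputs of one sample as TSV files
#'
#' Emits deterministic tab-separated files (`counts.tsv`,
#' `diagnostics.tsv`, `composition.tsv`, `mirna_normalized.tsv`,
#' `pirna_normalized.tsv`, `length_distribution.tsv`,
#' `pirna_first_base.tsv`) so that two runs on identical input are
#' byte-identical.
#'
#' @param profile A `small_rna_profile` from [profile_small_rna()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "small_rna_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(profile$counts$counts, file.path(dir, "counts.tsv"))
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(profile$counts$ambiguous, metric = "ambiguous"),
    dplyr::mutate(profile$counts$unassigned, metric = "unassigned",
                  tier = NA_character_)
  )
  readr::write_tsv(diagnostics, file.path(dir, "diagnostics.tsv"))
  readr::write_tsv(tidy(profile$composition), file.path(dir, "composition.tsv"))
  readr::write_tsv(profile$mirna_norm, file.path(dir, "mirna_normalized.tsv"))
  readr::write_tsv(profile$pirna_norm, file.path(dir, "pirna_normalized.tsv"))
  readr::write_tsv(profile$length_dist,
                   file.path(dir, "length_distribution.tsv"))
  readr::write_tsv(profile$pirna_bases,
                   file.path(dir, "pirna_first_base.tsv"))
  invisible(dir)
}
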