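#' Category and biotype composition of a sample
#'
#' Computes the fraction of annotated reads falling into each tier
#' ('small RNA', 'rRNA', 'other RNA') and, within each tier, the fraction
#' contributed by each biotype. The denominator for tier fractions is
#' either assigned reads only (default) or assigned plus ambiguous reads;
#' biotype fractions are always relative to the tier's assigned reads.
#' Zero denominators yield `NA` fractions (an explicit undefined marker,
#' never a silent 0).
#'
#' @param table A `count_table` from [count_reads()].
#' @param sample Sample name; defaults to the table's single sample.
#' @param denominator `"assigned_only"` or `"include_ambiguous"`.
#' @return A `composition_summary` object with tibbles `category`
#'   (`tier`, `reads`, `fraction`) and `biotype` (`tier`, `biotype`,
#'   `reads`, `fraction`), plus the denominator used.
#' @export
category_fractions <- function(table, sample = NULL,
                               denominator = c("assigned_only",
                                               "include_ambiguous")) {
  stopifnot(inherits(table, "count_table"))
  denominator <- match.arg(denominator)
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
  assigned_by_tier <- vapply(TIER_ORDER, function(t)
    sum(table$counts[[sample]][table$counts$tier == t]), numeric(1))
  amb <- table$ambiguous[table$ambiguous$sample == sample, , drop = FALSE]
  amb_by_tier <- setNames(amb$n[match(TIER_ORDER, amb$tier)], TIER_ORDER)
  amb_by_tier[is.na(amb_by_tier)] <- 0
  tier_reads <- assigned_by_tier
  if (denominator == "include_ambiguous") {
    tier_reads <- tier_reads + amb_by_tier
  }
  denom <- sum(tier_reads)
  if (denom == 0) {
    warn(sprintf("sample '%s' has no annotated reads; fractions are undefined",
                 sample))
  }
  category <- tibble::tibble(
    tier = TIER_ORDER,
    reads = as.integer(unname(tier_reads)),
    fraction = if (denom == 0) NA_real_ else unname(tier_reads) / denom
  )
  biotype <- table$counts |>
    dplyr::group_by(.data$tier, .data$biotype) |>
    dplyr::summarise(reads = sum(.data[[sample]]), .groups = "drop") |>
    dplyr::group_by(.data$tier) |>
    dplyr::mutate(fraction = if (sum(.data$reads) == 0) NA_real_ else
      .data$reads / sum(.data$reads)) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$tier, TIER_ORDER), .data$biotype)
  structure(
    list(sample = sample, denominator_mode = denominator,
         denominator = as.integer(denom), category = category,
         biotype = biotype),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("RNA composition of sample '%s' (%s denominator, %d reads)\n",
              x$sample, x$denominator_mode, x$denominator))
  print(x$category)
  invisible(x)
}

#' @export
tidy.composition_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$category, sample = x$sample, level = "category",
                  biotype = NA_character_),
    dplyr::mutate(x$biotype, sample = x$sample, level = "biotype")
  ) |>
    dplyr::select("sample", "level", "tier", "biotype", "reads", "fraction")
}

#' Read-length histograms per biotype or tier
#'
#' Histograms of sequence length over the 17-35 nt analysis window for
#' assigned reads, grouped by biotype (default) or tier.
#'
#' @param assignments Output of [assign_reads()]; must carry a `length`
#'   column.
#' @param group_by `"biotype"` or `"tier"`.
#' @param min_len,max_len Histogram support (defaults 17 and 35).
#' @return A tibble with `group`, `length` (complete over the window) and
#'   `count`.
#' @export
length_distribution <- function(assignments, group_by = c("biotype", "tier"),
                                min_len = 17L, max_len = 35L) {
  group_by <- match.arg(group_by)
  assigned <- dplyr::filter(assignments, .data$status == "assigned")
  groups <- sort(unique(assigned[[group_by]]))
  grid <- tidyr::expand_grid(group = groups, length = min_len:max_len)
  obs <- assigned |>
    dplyr::count(group = .data[[group_by]], length = .data$length)
  dplyr::left_join(grid, obs, by = c("group", "length")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$n, 0L), n = NULL)
}

#' Fraction of reads within a length sub-range
#'
#' @param dist A histogram tibble from [length_distribution()].
#' @param lower,upper Inclusive bounds of the queried sub-range.
#' @return A tibble with `group`, `total` and `fraction` (NA for empty
#'   groups).
#' @export
length_range_fraction <- function(dist, lower, upper) {
  dist |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      total = sum(.data$count),
      fraction = ifelse(sum(.data$count) == 0, NA_real_,
                        sum(.data$count[.data$length >= lower &
                                          .data$length <= upper]) /
                          sum(.data$count)),
      .groups = "drop"
    )
}

#' Positional base composition of assigned reads
#'
#' Computes per-position base fractions in biological read orientation
#' (position 1 is the 5' end; `-`-strand alignments are
#' reverse-complemented first). By default only position 1 is reported —
#' the statistic behind the 5'-uracil bias of mature piRNAs. The internal
#' alphabet is DNA; display as U instead of T is left to plotting.
#'
#' @param assignments Output of [assign_reads()] with a `sequence` column.
#' @param biotype Restrict to reads assigned to this biotype (`NULL` for
#'   all assigned reads).
#' @param full If `TRUE`, profile every position covered by at least one
#'   read; otherwise position 1 only.
#' @return A tibble with `position`, `base`, `count` and `fraction`
#'   (fractions sum to 1 per position with non-zero coverage).
#' @export
first_base_composition <- function(assignments, biotype = NULL,
                                   full = FALSE) {
  reads <- dplyr::filter(assignments, .data$status == "assigned")
  if (!is.null(biotype)) {
    bt <- biotype
    reads <- dplyr::filter(reads, .data$biotype == bt)
  }
  bases <- c("A", "C", "G", "T")
  if (nrow(reads) == 0) {
    return(tibble::tibble(position = integer(), base = character(),
                          count = integer(), fraction = double()))
  }
  seqs <- oriented_sequences(reads)
  positions <- if (full) seq_len(max(nchar(seqs))) else 1L
  purrr::map_dfr(positions, function(p) {
    ch <- substr(seqs, p, p)
    ch <- ch[nzchar(ch)]
    counts <- unname(vapply(bases, function(b) sum(ch == b), integer(1)))
    covered <- sum(counts)
    tibble::tibble(
      position = p, base = bases, count = counts,
      fraction = if (covered == 0) NA_real_ else counts / covered
    )
  })
}

#' Mature-piRNA criteria among piRNA-locus reads
#'
#' A read mapping to a piRNA locus is counted as compatible with a mature
#' piRNA when its length lies in the characteristic 27-35 nt range *and*
#' its 5' base is uracil. Reports the joint fraction and both marginal
#' fractions among piRNA-assigned reads.
#'
#' @param assignments Output of [assign_reads()].
#' @param min_len,max_len Mature size range (defaults 27 and 35).
#' @return A one-row tibble with `n_pirna_reads`, `length_fraction`,
#'   `five_prime_u_fraction` and `joint_fraction` (all `NA` when no piRNA
#'   reads exist).
#' @export
mature_pirna_fraction <- function(assignments, min_len = 27L, max_len = 35L) {
  reads <- dplyr::filter(assignments, .data$status == "assigned",
                         .data$biotype == "piRNA")
  if (nrow(reads) == 0) {
    warn("no piRNA-assigned reads; mature-piRNA fractions are undefined")
    return(tibble::tibble(n_pirna_reads = 0L, length_fraction = NA_real_,
                          five_prime_u_fraction = NA_real_,
                          joint_fraction = NA_real_))
  }
  len_ok <- reads$length >= min_len & reads$length <= max_len
  u_ok <- substr(oriented_sequences(reads), 1, 1) == "T"
  tibble::tibble(
    n_pirna_reads = nrow(reads),
    length_fraction = mean(len_ok),
    five_prime_u_fraction = mean(u_ok),
    joint_fraction = mean(len_ok & u_ok)
  )
}

#' Cumulative abundance coverage of top-ranked entries
#'
#' Sorts abundances in decreasing order (ties broken by key, for
#' determinism) and accumulates their share of the total. Answers both
#' "what fraction do the top `n` cover?" and "how many entries are needed
#' to cover `target_fraction` of the total?".
#'
#' @param values A named non-negative numeric vector, or a two-column data
#'   frame (key, value).
#' @param n Report the cumulative share of the top `n` entries.
#' @param target_fraction Report the minimal number of top entries whose
#'   cumulative share reaches this fraction.
#' @return A `cumulative_coverage` object with the full `curve` tibble
#'   (`key`, `value`, `share`, `cumulative`, `rank`), and — when requested
#'   — `top_n_share` and/or `n_for_target` with `share_at_target`.
#' @export
top_n_cumulative <- function(values, n = NULL, target_fraction = NULL) {
  if (is.data.frame(values)) {
    stopifnot(ncol(values) >= 2)
    keys <- as.character(values[[1]])
    vals <- as.numeric(values[[2]])
  } else {
    vals <- as.numeric(values)
    keys <- names(values) %||% sprintf("item%05d", seq_along(vals))
  }
  if (length(vals) == 0 || any(vals < 0)) {
    abort("`values` must be a non-empty collection of non-negative numbers")
  }
  total <- sum(vals)
  if (total == 0) {
    abort("all abundances are zero; cumulative coverage is undefined")
  }
  ord <- order(-vals, keys)
  curve <- tibble::tibble(
    key = keys[ord], value = vals[ord], share = vals[ord] / total,
    cumulative = cumsum(vals[ord] / total),
    rank = seq_along(ord)
  )
  out <- list(curve = curve, total = total)
  if (!is.null(n)) {
    if (n < 1 || n > nrow(curve)) {
      abort("`n` must be between 1 and the number of entries")
    }
    out$top_n <- as.integer(n)
    out$top_n_share <- curve$cumulative[n]
  }
  if (!is.null(target_fraction)) {
    check_fraction(target_fraction, "target_fraction")
    out$target_fraction <- target_fraction
    out$n_for_target <- which(curve$cumulative >= target_fraction - 1e-12)[1]
    out$share_at_target <- curve$cumulative[out$n_for_target]
  }
  structure(out, class = "cumulative_coverage")
}

#' @export
print.cumulative_coverage <- function(x, ...) {
  cat(sprintf("Cumulative coverage over %d entries (total %.4g)\n",
              nrow(x$curve), x$total))
  if (!is.null(x$top_n_share)) {
    cat(sprintf("  top %d cover %.4f of the total\n", x$top_n, x$top_n_share))
  }
  if (!is.null(x$n_for_target)) {
    cat(sprintf("  %d entries needed to cover %.2f (achieved %.4f)\n",
                x$n_for_target, x$target_fraction, x$share_at_target))
  }
  invisible(x)
}

#' @export
tidy.cumulative_coverage <- function(x, ...) x$curve

#' Pearson correlation between two normalised profiles
#'
#' @param a,b Named numeric vectors or two-column data frames
#'   (gene, fraction).
#' @param join `"union"` (default; genes absent from one profile enter as
#'   zero, mirroring scatter plots that include EV-enriched genes) or
#'   `"intersection"`.
#' @param min_genes Minimum number of paired genes required (default 3).
#' @return The Pearson correlation, or `NA` with a warning when either
#'   paired vector has zero variance.
#' @export
sample_correlation <- function(a, b, join = c("union", "intersection"),
                               min_genes = 3L) {
  join <- match.arg(join)
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(as.numeric(x[[2]]), as.character(x[[1]]))
    else x
  }
  a <- as_named(a)
  b <- as_named(b)
  genes <- if (join == "union") union(names(a), names(b)) else
    intersect(names(a), names(b))
  if (length(genes) < min_genes) {
    abort(sprintf("only %d gene(s) after the %s join; at least %d required",
                  length(genes), join, min_genes))
  }
  va <- ifelse(is.na(a[genes]), 0, a[genes])
  vb <- ifelse(is.na(b[genes]), 0, b[genes])
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warn("zero variance in one of the profiles; correlation is undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Hierarchical clustering of samples on one-minus-Pearson distances
#'
#' Genes with zero counts throughout the tested samples are excluded, the
#' pairwise distance is `1 - Pearson(i, j)` (range 0 to 2) and samples are
#' clustered agglomeratively with average linkage by default. The leaf
#' order is deterministic: `stats::hclust()` resolves ties by input order,
#' and samples are taken in the row order given.
#'
#' @param profiles A samples-by-genes numeric matrix with sample row
#'   names, or a data frame whose first column is the sample name.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A `pearson_hclust` object holding the `hclust` tree, the
#'   distance matrix and the number of genes used/dropped.
#' @export
hierarchical_cluster <- function(profiles, linkage = "average") {
  if (is.data.frame(profiles)) {
    m <- as.matrix(profiles[, -1, drop = FALSE])
    rownames(m) <- as.character(profiles[[1]])
  } else {
    m <- as.matrix(profiles)
  }
  if (nrow(m) < 2) {
    abort("at least 2 samples are required for clustering")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("sample%d", seq_len(nrow(m)))
  }
  zero_gene <- colSums(m != 0) == 0
  m <- m[, !zero_gene, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("sample(s) with zero variance after gene filtering: %s",
                  paste(rownames(m)[sds == 0], collapse = ", ")))
  }
  d <- 1 - stats::cor(t(m))
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(
    list(hclust = tree, distance = d, linkage = linkage,
         n_genes_used = ncol(m), n_genes_dropped = sum(zero_gene)),
    class = "pearson_hclust"
  )
}

#' @export
print.pearson_hclust <- function(x, ...) {
  cat(sprintf(
    "Hierarchical clustering of %d samples (1 - Pearson, %s linkage; %d genes, %d all-zero genes dropped)\n",
    nrow(x$distance), x$linkage, x$n_genes_used, x$n_genes_dropped))
  print(x$hclust)
  invisible(x)
}

#' @export
tidy.pearson_hclust <- function(x, ...) {
  tree <- x$hclust
  tibble::tibble(
    step = seq_len(nrow(tree$merge)),
    left = tree$merge[, 1],
    right = tree$merge[, 2],
    height = tree$height
  )
}

#' @export
glance.pearson_hclust <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$distance),
    n_genes_used = x$n_genes_used,
    n_genes_dropped = x$n_genes_dropped,
    linkage = x$linkage,
    max_distance = max(x$distance)
  )
}
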