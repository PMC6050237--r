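#' Load a protein abundance table
#'
#' Reads a TSV with columns `protein_id` and `ms_area` (optionally
#' `gene_name`). Protein identifiers must be unique within a sample —
#' the analysis is based on unique protein identifiers, so isoforms are
#' distinct records. Zero-abundance rows are retained; negative abundances
#' are an error.
#'
#' @param path TSV file path.
#' @return A tibble with `protein_id`, `ms_area` and, if present,
#'   `gene_name`.
#' @export
read_protein_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read protein table: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    ms_area = readr::col_double(),
    .default = readr::col_character()
  ))
  if (!all(c("protein_id", "ms_area") %in% names(tab))) {
    abort("protein table must have columns 'protein_id' and 'ms_area'")
  }
  if (anyDuplicated(tab$protein_id)) {
    abort(sprintf("duplicated protein_id(s): %s",
                  paste(head(unique(tab$protein_id[duplicated(tab$protein_id)]), 3),
                        collapse = ", ")))
  }
  neg <- which(tab$ms_area < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative ms_area in row %d (protein %s)",
                  neg[1], tab$protein_id[neg[1]]))
  }
  tab
}

#' MS-Area abundance shares and ranks
#'
#' A protein's abundance share is its MS Area over the total MS Area of
#' the sample proteome. Ranks are 1..n in decreasing abundance, ties
#' broken by protein id for determinism.
#'
#' @param proteins A protein tibble (see [read_protein_table()]).
#' @return The tibble sorted by rank, with `share` and `rank` columns
#'   added; shares sum to 1.
#' @export
abundance_shares <- function(proteins) {
  total <- sum(proteins$ms_area)
  if (total <= 0) {
    abort("total MS Area is zero; abundance shares are undefined")
  }
  ord <- order(-proteins$ms_area, proteins$protein_id)
  out <- proteins[ord, , drop = FALSE]
  out$share <- out$ms_area / total
  out$rank <- seq_len(nrow(out))
  tibble::as_tibble(out)
}

#' Minimal number of top proteins covering a mass fraction
#'
#' How many of the most abundant proteins (by MS Area) are needed so that
#' their cumulative abundance share reaches `target_fraction` of the total
#' protein mass.
#'
#' @param proteins A protein tibble.
#' @param target_fraction Target cumulative share (default 0.75).
#' @return A one-row tibble with `n_proteins` and `cumulative_share`.
#' @export
proteins_covering <- function(proteins, target_fraction = 0.75) {
  cc <- top_n_cumulative(
    setNames(proteins$ms_area, proteins$protein_id),
    target_fraction = target_fraction
  )
  tibble::tibble(n_proteins = cc$n_for_target,
                 cumulative_share = cc$share_at_target)
}

#' Construct a GO term set
#'
#' A named collection of GO terms (e.g. the custom 'miRNA related' slim
#' built from 50 terms, or 'RNA binding') together with the proteins
#' annotated to any member term.
#'
#' @param set_name Display name of the set.
#' @param term_ids Non-empty character vector of GO identifiers.
#' @param protein_ids Proteins annotated to any member term.
#' @return A `go_term_set` object.
#' @export
go_term_set <- function(set_name, term_ids, protein_ids = character()) {
  if (length(term_ids) == 0) {
    abort("`term_ids` must be non-empty")
  }
  structure(
    list(set_name = set_name, term_ids = unique(term_ids),
         protein_ids = unique(protein_ids)),
    class = "go_term_set"
  )
}

#' Fraction and abundance share of a protein set
#'
#' Computes the count fraction (set members over all identified proteins)
#' and the abundance share (summed MS-Area shares of the members) of a GO
#' term set within a sample proteome.
#'
#' @param proteins A protein tibble.
#' @param term_set A [go_term_set()] (or a character vector of protein
#'   ids).
#' @return A one-row tibble with `set_name`, `n_members`, `count_fraction`
#'   and `abundance_share`.
#' @export
set_fraction <- function(proteins, term_set) {
  if (nrow(proteins) == 0) {
    abort("`proteins` must be non-empty")
  }
  if (inherits(term_set, "go_term_set")) {
    ids <- term_set$protein_ids
    nm <- term_set$set_name
  } else {
    ids <- term_set
    nm <- NA_character_
  }
  member <- proteins$protein_id %in% ids
  shares <- abundance_shares(proteins)
  tibble::tibble(
    set_name = nm,
    n_members = sum(member),
    count_fraction = mean(member),
    abundance_share = sum(shares$share[shares$protein_id %in% ids])
  )
}

#' Overlap between a sample proteome and a reference database
#'
#' Exact set arithmetic on protein identifier sets, e.g. sample
#' identifications against a community EV database restricted to
#' experiments with at least 500 identified proteins. Identifier
#' namespaces must already be harmonised.
#'
#' @param sample_ids,reference_ids Character vectors of protein ids.
#' @return A one-row tibble with `only_sample`, `intersection`,
#'   `only_reference` and `overlap_fraction` (of the sample).
#' @export
venn_overlap <- function(sample_ids, reference_ids) {
  sample_ids <- unique(sample_ids)
  reference_ids <- unique(reference_ids)
  both <- intersect(sample_ids, reference_ids)
  tibble::tibble(
    only_sample = length(setdiff(sample_ids, reference_ids)),
    intersection = length(both),
    only_reference = length(setdiff(reference_ids, sample_ids)),
    overlap_fraction = if (length(sample_ids) == 0) NA_real_ else
      length(both) / length(sample_ids)
  )
}

normalize_term_map <- function(term_map) {
  if (is.data.frame(term_map)) {
    stopifnot(all(c("term", "protein_id") %in% names(term_map)))
    split(as.character(term_map$protein_id), as.character(term_map$term))
  } else if (is.list(term_map)) {
    term_map
  } else {
    abort("`term_map` must be a tibble (term, protein_id) or a named list")
  }
}

#' GO-term overrepresentation test
#'
#' Tests each term for overrepresentation of its members in a target
#' protein list against a reference list (typically all protein
#' identifications of the sample). Fold enrichment is `(k/n) / (K/N)` with
#' `n = |target|`, `N = |reference|` and `k`/`K` the term members in
#' target/reference. The p-value is the one-sided hypergeometric tail
#' `P(X >= k)` (equivalently a one-sided Fisher exact test); a binomial
#' tail `P(Bin(n, K/N) >= k)` is available as an alternative. P-values
#' are adjusted across terms by Benjamini-Hochberg.
#'
#' @param target Character vector of target protein ids (must be a subset
#'   of `reference`).
#' @param reference Character vector of reference protein ids.
#' @param term_map A tibble with columns `term` and `protein_id`, or a
#'   named list of protein-id vectors. Memberships outside the reference
#'   are ignored; every term must retain at least one reference protein.
#' @param test `"hypergeometric"` (default) or `"binomial"`.
#' @return A tibble with one row per term: `term`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`, `p_adjusted`, sorted by p-value.
#' @export
overrepresentation_test <- function(target, reference, term_map,
                                    test = c("hypergeometric", "binomial")) {
  test <- match.arg(test)
  target <- unique(target)
  reference <- unique(reference)
  if (!all(target %in% reference)) {
    abort("`target` must be a subset of `reference`")
  }
  terms <- normalize_term_map(term_map)
  terms <- lapply(terms, function(ids) intersect(unique(ids), reference))
  empty <- names(terms)[lengths(terms) == 0]
  if (length(empty) > 0) {
    abort(sprintf("term(s) with no protein in the reference: %s",
                  paste(head(empty, 5), collapse = ", ")))
  }
  n <- length(target)
  N <- length(reference)
  k <- unname(vapply(terms, function(ids) sum(target %in% ids), integer(1)))
  K <- unname(lengths(terms))
  p <- if (test == "hypergeometric") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
  }
  tibble::tibble(
    term = names(terms), k = k, K = K, n = n, N = N,
    fold_enrichment = (k / n) / (K / N),
    p_value = p,
    p_adjusted = stats::p.adjust(p, method = "BH")
  ) |>
    dplyr::arrange(.data$p_value, .data$term)
}

#' Rank-based abundance enrichment of term members
#'
#' A rank-based analogue of expression-aware enrichment analysis: for each
#' term, the MS-Area abundance ranks of member proteins are compared with
#' those of non-members by a two-sided Mann-Whitney U test. This accounts
#' for *how abundant* members are, not merely whether they were detected.
#'
#' @param proteins A protein tibble.
#' @param term_map As in [overrepresentation_test()].
#' @return A tibble with `term`, `n_members`, `median_member_rank`,
#'   `median_other_rank`, `p_value` and `p_adjusted` (BH). Terms without
#'   both members and non-members get `NA` p-values.
#' @export
abundance_rank_enrichment <- function(proteins, term_map) {
  shares <- abundance_shares(proteins)
  terms <- normalize_term_map(term_map)
  res <- purrr::map_dfr(names(terms), function(nm) {
    member <- shares$protein_id %in% terms[[nm]]
    p <- if (sum(member) > 0 && sum(!member) > 0) {
      suppressWarnings(
        stats::wilcox.test(shares$rank[member], shares$rank[!member])$p.value)
    } else {
      NA_real_
    }
    tibble::tibble(
      term = nm, n_members = sum(member),
      median_member_rank = if (any(member)) median(shares$rank[member]) else
        NA_real_,
      median_other_rank = if (any(!member)) median(shares$rank[!member]) else
        NA_real_,
      p_value = p
    )
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$term)
}

#' Curation of proteins by GO child terms
#'
#' Summarises the identified proteins within each supplied child term of a
#' parent class (e.g. the child terms of 'RNA binding'): how many proteins
#' fall in the term, their summed abundance share and their abundance-rank
#' distribution. Term membership is explicitly non-exclusive — one protein
#' may appear under several child terms (rRNA binding *and* mRNA binding,
#' say) — so abundance shares may sum to more than 1 across terms. Empty
#' terms are retained as zero rows.
#'
#' @param proteins A protein tibble.
#' @param term_map Child-term protein lists, as in
#'   [overrepresentation_test()] (ontology-graph traversal is not
#'   performed; the lists are inputs).
#' @return A tibble with `term`, `n_proteins`, `abundance_share`,
#'   `min_rank`, `median_rank` and `mean_rank`, sorted by decreasing
#'   abundance share.
#' @export
child_term_curation <- function(proteins, term_map) {
  shares <- abundance_shares(proteins)
  terms <- normalize_term_map(term_map)
  purrr::map_dfr(names(terms), function(nm) {
    member <- shares$protein_id %in% terms[[nm]]
    tibble::tibble(
      term = nm,
      n_proteins = sum(member),
      abundance_share = sum(shares$share[member]),
      min_rank = if (any(member)) min(shares$rank[member]) else NA_integer_,
      median_rank = if (any(member)) median(shares$rank[member]) else NA_real_,
      mean_rank = if (any(member)) mean(shares$rank[member]) else NA_real_
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$abundance_share), .data$term)
}
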