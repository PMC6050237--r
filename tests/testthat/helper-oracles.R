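# Brute-force reference implementations and fixture builders used across
# the tests. These deliberately avoid the package's interval indexes so
# they stay independent of the code paths they check.

make_features <- function(chrom, start, end, strand, gene_id,
                          biotype, source = "test") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, gene_id = gene_id, gene_name = gene_id,
    biotype = biotype, source = source
  )
}

# linear-scan overlap: indices of features overlapping the read on-strand
oracle_overlapping_features <- function(read, features, min_overlap = 1L) {
  ov <- pmin(read$end, features$end) - pmax(read$start, features$start)
  which(features$chrom == read$chrom & features$strand == read$strand &
          ov >= min_overlap)
}

# full cascade by linear scan: min-tier subset, within-tier uniqueness
oracle_assign_one <- function(read, features, config,
                              min_overlap = 1L) {
  hits <- oracle_overlapping_features(read, features, min_overlap)
  if (length(hits) == 0) {
    return(list(status = "unassigned", tier = NA_character_,
                gene_id = NA_character_, candidates = character()))
  }
  tiers <- unname(config[features$biotype[hits]])
  best <- c("small_rna", "rrna", "other_rna")[
    min(match(tiers, c("small_rna", "rrna", "other_rna")))]
  in_tier <- hits[tiers == best]
  genes <- sort(unique(features$gene_id[in_tier]))
  if (length(genes) == 1) {
    list(status = "assigned", tier = best, gene_id = genes,
         candidates = genes)
  } else {
    list(status = "ambiguous", tier = best, gene_id = NA_character_,
         candidates = genes)
  }
}

# pairwise reciprocal-overlap filter (double loop)
oracle_reciprocal_filter <- function(candidates, reference, min_fraction) {
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(reference))) {
      if (candidates$chrom[i] != reference$chrom[j]) next
      if (candidates$strand[i] != reference$strand[j]) next
      ov <- min(candidates$end[i], reference$end[j]) -
        max(candidates$start[i], reference$start[j])
      if (ov <= 0) next
      if (ov >= min_fraction * (candidates$end[i] - candidates$start[i]) &&
          ov >= min_fraction * (reference$end[j] - reference$start[j])) {
        keep[i] <- FALSE
      }
    }
  }
  candidates[keep, , drop = FALSE]
}

# brute-force 3' adapter scan mirroring the documented trimming rule
oracle_trim_point <- function(seq, adapter, max_error_rate = 0.1,
                              min_overlap = 3L) {
  L <- nchar(seq)
  m <- nchar(adapter)
  best <- list(i = 0L, score = Inf)
  for (i in seq_len(L)) {
    l <- min(m, L - i + 1L)
    if (l < min_overlap) next
    s <- substr(seq, i, i + l - 1L)
    a <- substr(adapter, 1L, l)
    mm <- sum(strsplit(s, "")[[1]] != strsplit(a, "")[[1]])
    if (mm / l <= max_error_rate && mm / l < best$score) {
      best <- list(i = i, score = mm / l)
    }
  }
  best$i
}

random_annotation <- function(n_features, seed, chroms = c("chr1", "chr2", "chr3"),
                              chrom_len = 100000L) {
  vocab <- unlist(default_tier_vocabulary(), use.names = FALSE)
  withr::with_seed(seed, {
    len <- sample(50:300, n_features, replace = TRUE)
    start <- sample.int(chrom_len - 400L, n_features, replace = TRUE)
    make_features(
      chrom = sample(chroms, n_features, replace = TRUE),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n_features, replace = TRUE),
      gene_id = sprintf("g%05d", sample.int(max(2L, n_features %/% 2L),
                                            n_features, replace = TRUE)),
      biotype = sample(vocab, n_features, replace = TRUE)
    )
  })
}

random_reads <- function(n_reads, seed, chroms = c("chr1", "chr2", "chr3"),
                         chrom_len = 100000L) {
  withr::with_seed(seed, {
    len <- sample(17:35, n_reads, replace = TRUE)
    start <- sample.int(chrom_len - 40L, n_reads, replace = TRUE)
    tibble::tibble(
      read_id = sprintf("r%06d", seq_len(n_reads)),
      chrom = sample(chroms, n_reads, replace = TRUE),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      sequence = strrep("A", len), length = len
    )
  })
}

# vectorised brute-force cascade over a whole read set: dense pairwise
# overlap per (chromosome, strand) group, then explicit priority and
# uniqueness rules. Used by the cascade-equivalence checks.
oracle_assign_all <- function(reads, features, config, min_overlap = 1L) {
  n <- nrow(reads)
  status <- rep("unassigned", n)
  tier <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  cand_key <- rep("", n)
  tier_rank <- match(unname(config[features$biotype]), TIER_LEVELS)
  for (cn in unique(reads$chrom)) {
    for (st in c("+", "-")) {
      ri <- which(reads$chrom == cn & reads$strand == st)
      fi <- which(features$chrom == cn & features$strand == st)
      if (length(ri) == 0 || length(fi) == 0) next
      ov <- outer(reads$end[ri], features$end[fi], pmin) -
        outer(reads$start[ri], features$start[fi], pmax)
      hit <- which(ov >= min_overlap, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      df <- data.frame(r = hit[, 1], f = fi[hit[, 2]])
      df$rank <- tier_rank[df$f]
      min_rank <- tapply(df$rank, df$r, min)
      df <- df[df$rank == min_rank[as.character(df$r)], , drop = FALSE]
      genes <- split(features$gene_id[df$f], df$r)
      genes <- lapply(genes, function(g) sort(unique(g)))
      idx <- ri[as.integer(names(genes))]
      ng <- lengths(genes)
      tier[idx] <- TIER_LEVELS[min_rank[names(genes)]]
      status[idx] <- ifelse(ng == 1, "assigned", "ambiguous")
      gene_id[idx[ng == 1]] <- unlist(genes[ng == 1], use.names = FALSE)
      cand_key[idx] <- vapply(genes, paste, "", collapse = "|")
    }
  }
  tibble::tibble(read_id = reads$read_id, status = status, tier = tier,
                 gene_id = gene_id, cand_key = cand_key)
}

TIER_LEVELS <- c("small_rna", "rrna", "other_rna")

assignment_key <- function(assignments) {
  tibble::tibble(
    read_id = assignments$read_id,
    status = assignments$status,
    tier = assignments$tier,
    gene_id = assignments$gene_id,
    cand_key = vapply(assignments$candidate_gene_ids, paste, "",
                      collapse = "|")
  )
}
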