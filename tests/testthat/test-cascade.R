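toy_annotation <- function() {
  build_tiered_annotation(make_features(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(100, 100, 500, 500, 900),
    end = c(200, 200, 600, 600, 1000),
    strand = c("+", "+", "+", "+", "+"),
    gene_id = c("mir-1", "tRNA-Gly-GCC-1", "piR-1", "piR-2", "rRNA-1"),
    biotype = c("miRNA", "tRNA", "piRNA", "piRNA", "rRNA_LSU")
  ))
}

one_read <- function(chrom, start, end, strand = "+", id = "r1") {
  tibble::tibble(read_id = id, chrom = chrom, start = start, end = end,
                 strand = strand, sequence = strrep("A", end - start),
                 length = end - start)
}

test_that("cascade respects tier priority, strand and passthrough rules", {
  ann <- toy_annotation()
  # read over a miRNA and a tRNA locus: the small-RNA tier wins and the
  # tRNA is never consulted
  a <- assign_reads(one_read("chr1", 120, 142), ann)
  expect_equal(a$status, "assigned")
  expect_equal(a$gene_id, "mir-1")
  expect_equal(a$tier, "small_rna")

  # two distinct piRNA genes at the same locus: ambiguous in tier 1 and
  # the read does NOT continue down the cascade
  a <- assign_reads(one_read("chr1", 520, 545), ann)
  expect_equal(a$status, "ambiguous")
  expect_equal(a$tier, "small_rna")
  expect_equal(a$candidate_gene_ids[[1]], c("piR-1", "piR-2"))
  expect_true(is.na(a$gene_id))

  # no overlap anywhere: unassigned with no tier
  a <- assign_reads(one_read("chr1", 5000, 5022), ann)
  expect_equal(a$status, "unassigned")
  expect_true(is.na(a$tier))

  # stranded mode: an antisense read does not hit the feature
  a <- assign_reads(one_read("chr1", 120, 142, strand = "-"), ann)
  expect_equal(a$status, "unassigned")

  # minimum-overlap knob: a 1-base overlap hits by default, not at 10
  a1 <- assign_reads(one_read("chr1", 199, 221), ann)
  expect_equal(a1$status, "assigned")
  a10 <- assign_reads(one_read("chr1", 199, 221), ann, min_overlap = 10L)
  expect_equal(a10$status, "unassigned")
})

test_that("cascade equals the brute-force oracle on randomized instances", {
  cfg <- build_tier_config()
  for (seed in c(1, 2, 3)) {
    feats <- random_annotation(400, seed)
    feats <- feats[!duplicated(feats[c("chrom", "start", "end", "strand",
                                       "gene_id")]), ]
    ann <- build_tiered_annotation(feats)
    reads <- random_reads(800, seed + 50)
    got <- assignment_key(assign_reads(reads, ann))
    want <- oracle_assign_all(reads, ann$features, cfg)
    expect_equal(got$status, want$status)
    expect_equal(got$tier, want$tier)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$cand_key, want$cand_key)
  }
})

test_that("removing tier-1 features only demotes reads down the cascade", {
  feats <- random_annotation(400, seed = 9)
  feats <- feats[!duplicated(feats[c("chrom", "start", "end", "strand",
                                     "gene_id")]), ]
  ann_full <- build_tiered_annotation(feats)
  ann_masked <- build_tiered_annotation(
    feats[!unname(ann_full$config[feats$biotype]) == "small_rna", ])
  reads <- random_reads(600, seed = 10)
  full <- assign_reads(reads, ann_full)
  masked <- assign_reads(reads, ann_masked)
  rank_of <- function(tier) ifelse(is.na(tier), 4L, match(tier, TIER_LEVELS))
  expect_true(all(rank_of(masked$tier) >= rank_of(full$tier)))
  # reads untouched by tier 1 keep their outcome exactly
  untouched <- full$tier != "small_rna" | is.na(full$tier)
  expect_equal(masked$status[untouched], full$status[untouched])
  expect_equal(masked$gene_id[untouched], full$gene_id[untouched])
})

test_that("counting conserves reads and orders rows deterministically", {
  ann <- toy_annotation()
  reads <- dplyr::bind_rows(
    one_read("chr1", 120, 142, id = "r1"),
    one_read("chr1", 125, 147, id = "r2"),
    one_read("chr1", 130, 152, id = "r3"),
    one_read("chr1", 520, 545, id = "r4"),     # ambiguous
    one_read("chr1", 5000, 5022, id = "r5")    # unassigned
  )
  asn <- assign_reads(reads, ann)
  tab <- count_reads(asn, sample = "s1")
  expect_equal(tab$counts$s1[tab$counts$gene_id == "mir-1"], 3L)
  expect_equal(sum(tab$ambiguous$n), 1L)
  expect_equal(tab$unassigned$n, 1L)
  expect_equal(sum(tab$counts$s1) + sum(tab$ambiguous$n) + tab$unassigned$n,
               nrow(reads))

  empty <- count_reads(asn[0, ], sample = "s0")
  expect_equal(nrow(empty$counts), 0)
  expect_equal(sum(empty$ambiguous$n), 0L)

  # multi-sample merge keeps keys aligned and zero-fills
  tab2 <- count_reads(asn[1:2, ], sample = "s2")
  both <- bind_count_tables(tab, tab2)
  expect_equal(both$counts$s2[both$counts$gene_id == "mir-1"], 2L)
  expect_equal(sum(both$counts$s2), 2L)
})

test_that("isoacceptor pooling merges loci and conserves totals", {
  counts <- tibble::tibble(
    gene_id = c("tRNA-Gly-GCC-1", "tRNA-Gly-GCC-7", "tRNA-Gly-CCC-2",
                "mir-1", "oddball"),
    biotype = c("tRNA", "tRNA", "tRNA", "miRNA", "tRNA"),
    tier = c("other_rna", "other_rna", "other_rna", "small_rna", "other_rna"),
    s1 = c(5L, 7L, 4L, 9L, 2L)
  )
  tab <- evcargo:::new_count_table(
    counts,
    tibble::tibble(sample = "s1", tier = TIER_LEVELS, n = c(0L, 0L, 0L)),
    tibble::tibble(sample = "s1", n = 0L)
  )
  expect_warning(pooled <- pool_trna_isoacceptors(tab), "oddball")
  pc <- pooled$counts
  expect_equal(pc$s1[pc$gene_id == "tRNA-Gly-GCC"], 12L)
  # different anticodons stay separate
  expect_equal(pc$s1[pc$gene_id == "tRNA-Gly-CCC"], 4L)
  expect_equal(sum(pc$s1), sum(counts$s1))
  expect_true("oddball" %in% pc$gene_id)

  # random partition of counts over loci of 3 isoacceptors
  withr::with_seed(21, {
    fam <- sample(c("Gly-GCC", "Glu-CTC", "His-GTG"), 10, replace = TRUE)
    cnt <- as.integer(sample(0:20, 10, replace = TRUE))
  })
  rnd <- evcargo:::new_count_table(
    tibble::tibble(
      gene_id = sprintf("tRNA-%s-%d", fam, seq_along(fam)),
      biotype = "tRNA", tier = "other_rna", s1 = cnt),
    tibble::tibble(sample = "s1", tier = TIER_LEVELS, n = 0L),
    tibble::tibble(sample = "s1", n = 0L)
  )
  pooled <- pool_trna_isoacceptors(rnd)
  want <- tapply(cnt, fam, sum)
  for (f in names(want)) {
    expect_equal(pooled$counts$s1[pooled$counts$gene_id ==
                                    sprintf("tRNA-%s", f)],
                 as.integer(want[[f]]))
  }
})

test_that("threshold normalisation divides by the full biotype total", {
  counts <- tibble::tibble(
    gene_id = c("a", "b", "c"), biotype = "miRNA", tier = "small_rna",
    s1 = c(6L, 3L, 2L)
  )
  tab <- evcargo:::new_count_table(
    counts, tibble::tibble(sample = "s1", tier = TIER_LEVELS, n = 0L),
    tibble::tibble(sample = "s1", n = 0L))
  norm <- threshold_normalize(tab, "miRNA")
  # genes >= 3 reads over the total of 11, sub-threshold gene omitted
  expect_equal(setNames(norm$fraction, norm$gene_id),
               c(a = 6 / 11, b = 3 / 11))

  one <- tab
  one$counts <- counts[1, ]
  one$counts$s1 <- 10L
  expect_equal(threshold_normalize(one, "miRNA")$fraction, 1.0)

  below <- tab
  below$counts$s1 <- c(2L, 1L, 2L)
  expect_equal(nrow(threshold_normalize(below, "miRNA")), 0)

  expect_warning(out <- threshold_normalize(tab, "piRNA"), "no piRNA")
  expect_equal(nrow(out), 0)

  # property: sums <= 1 with equality iff nothing fell below threshold
  for (seed in 31:34) {
    withr::with_seed(seed, cnt <- as.integer(rpois(20, 4)))
    t2 <- evcargo:::new_count_table(
      tibble::tibble(gene_id = sprintf("g%02d", 1:20), biotype = "piRNA",
                     tier = "small_rna", s1 = cnt),
      tibble::tibble(sample = "s1", tier = TIER_LEVELS, n = 0L),
      tibble::tibble(sample = "s1", n = 0L))
    norm <- threshold_normalize(t2, "piRNA")
    expect_lte(sum(norm$fraction), 1 + 1e-12)
    if (all(cnt[cnt > 0] >= 3) && any(cnt >= 3)) {
      expect_equal(sum(norm$fraction), 1)
    }
    if (any(cnt > 0 & cnt < 3)) {
      expect_lt(sum(norm$fraction), 1)
    }
  }
})

test_that("cross-biotype ambiguity counts cascade-masked overlaps per read", {
  # no overlapping piRNA/tRNA loci -> 0
  ann <- toy_annotation()
  reads <- dplyr::bind_rows(
    one_read("chr1", 505, 530, id = "r1"),
    one_read("chr1", 120, 142, id = "r2")
  )
  asn <- assign_reads(reads, ann)
  out <- cross_biotype_ambiguity(asn, ann, "piRNA", "tRNA")
  expect_equal(out$fraction, 0)
  expect_error(cross_biotype_ambiguity(asn, ann, "piRNA", "nonsense"),
               "unknown biotype")

  # construction: every piRNA locus nested in a tRNA locus; piRNA reads
  # are 10% of annotated reads -> fraction 0.10
  feats <- make_features(
    chrom = "chr1", start = c(100, 110, 1000), end = c(300, 170, 1100),
    strand = "+", gene_id = c("tRNA-Gly-GCC-1", "piR-1", "mir-1"),
    biotype = c("tRNA", "piRNA", "miRNA"))
  ann2 <- build_tiered_annotation(feats)
  reads2 <- dplyr::bind_rows(
    one_read("chr1", 120, 145, id = "p1"),
    lapply(1:9, function(i) one_read("chr1", 1010, 1032,
                                     id = sprintf("m%d", i)))
  )
  asn2 <- assign_reads(reads2, ann2)
  out2 <- cross_biotype_ambiguity(asn2, ann2, "piRNA", "tRNA")
  expect_equal(out2$fraction, 0.10)

  # synthetic annotation with a known fraction of nested piRNA loci:
  # recount from the generator's truth table
  gen <- generate_annotation(overlap_fraction = 0.3, seed = 4)
  ann3 <- build_tiered_annotation(gen$features)
  sim <- generate_reads(preset_ev_like(n_reads = 4000, seed = 5), ann3)
  asn3 <- assign_reads(sim$reads, ann3)
  got <- cross_biotype_ambiguity(asn3, ann3, "piRNA", "tRNA")
  nested <- gen$truth$overlaps
  truth_cross <- vapply(seq_len(nrow(asn3)), function(i) {
    if (asn3$status[i] != "assigned" || asn3$biotype[i] != "piRNA")
      return(FALSE)
    trna <- ann3$features[ann3$features$biotype == "tRNA", ]
    length(oracle_overlapping_features(asn3[i, ], trna)) > 0
  }, logical(1))
  expect_equal(got$n_cross, sum(truth_cross))
  expect_equal(got$fraction,
               sum(truth_cross) / sum(asn3$status %in% c("assigned",
                                                         "ambiguous")))
})
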