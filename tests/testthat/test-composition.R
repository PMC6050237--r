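fake_count_table <- function(small = 80L, rrna = 8L, other = 12L,
                             sample = "s1") {
  counts <- tibble::tibble(
    gene_id = c("mir-1", "rRNA-1", "tRNA-Gly-GCC"),
    biotype = c("miRNA", "rRNA_LSU", "tRNA"),
    tier = c("small_rna", "rrna", "other_rna")
  )
  counts[[sample]] <- c(small, rrna, other)
  evcargo:::new_count_table(
    counts[counts[[sample]] > 0 | TRUE, ],
    tibble::tibble(sample = sample, tier = TIER_LEVELS, n = 0L),
    tibble::tibble(sample = sample, n = 0L)
  )
}

test_that("category fractions recover the tier shares of the count table", {
  cf <- category_fractions(fake_count_table())
  expect_equal(cf$category$fraction, c(0.80, 0.08, 0.12))
  expect_equal(sum(cf$category$fraction), 1)
  # biotype fractions are within-tier and sum to 1 per occupied tier
  expect_equal(cf$biotype$fraction, c(1, 1, 1))

  # all reads in one tier
  cf1 <- category_fractions(fake_count_table(100L, 0L, 0L))
  expect_equal(cf1$category$fraction, c(1, 0, 0))

  # zero denominator: undefined marker, not zero
  expect_warning(cf0 <- category_fractions(fake_count_table(0L, 0L, 0L)),
                 "undefined")
  expect_true(all(is.na(cf0$category$fraction)))

  # ambiguous reads enter the denominator only on request
  tab <- fake_count_table()
  tab$ambiguous$n <- c(50L, 0L, 0L)
  strict <- category_fractions(tab, denominator = "assigned_only")
  loose <- category_fractions(tab, denominator = "include_ambiguous")
  expect_equal(strict$category$fraction[1], 0.80)
  expect_equal(loose$category$fraction[1], (80 + 50) / 150)
  expect_equal(sum(loose$category$fraction), 1)
})

test_that("tier and biotype fractions recover a generated mixture", {
  # moderate-n mixture recovery at 3 multinomial standard errors
  spec <- preset_ev_like(n_reads = 20000, seed = 77)
  ann <- build_tiered_annotation(generate_annotation(seed = 6)$features)
  sim <- generate_reads(spec, ann)
  prof <- profile_small_rna(sim$reads, ann, sample = "ev")
  cf <- prof$composition
  for (t in TIER_LEVELS) {
    p <- spec$tier_mixture[[t]]
    se <- sqrt(p * (1 - p) / spec$n_reads)
    expect_lt(abs(cf$category$fraction[cf$category$tier == t] - p), 3 * se)
  }
})

test_that("length histograms cover the window and report range fractions", {
  ann <- toy_len_ann <- build_tiered_annotation(make_features(
    "chr1", 100, 400, "+", "mir-1", "miRNA"))
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:5), chrom = "chr1", start = 150,
    end = 150 + 22, strand = "+", sequence = strrep("A", 22), length = 22L)
  asn <- assign_reads(reads, ann)
  dist <- length_distribution(asn)
  expect_equal(dist$length, 17:35)
  expect_equal(sum(dist$count), 5)
  expect_equal(dist$count[dist$length == 22], 5)
  fr <- length_range_fraction(dist, 20, 25)
  expect_equal(fr$fraction, 1.0)
  expect_equal(length_range_fraction(dist, 17, 19)$fraction, 0)

  # empty group: zero histogram
  dist0 <- length_distribution(asn[0, ])
  expect_equal(nrow(dist0), 0)

  # generator truth: miRNA length model puts 97% of reads in 20-25
  sim <- generate_reads(preset_cell_like(n_reads = 10000, seed = 12),
                        build_tiered_annotation(
                          generate_annotation(seed = 6)$features))
  asn <- assign_reads(sim$reads, build_tiered_annotation(
    generate_annotation(seed = 6)$features))
  fr <- length_range_fraction(length_distribution(asn), 20, 25)
  mi <- fr$fraction[fr$group == "miRNA"]
  expect_lt(abs(mi - 0.97), 3 * sqrt(0.97 * 0.03 / fr$total[fr$group == "miRNA"]))
})

test_that("5' base composition is computed in read orientation", {
  ann <- build_tiered_annotation(make_features(
    "chr1", c(100, 500), c(400, 800), c("+", "-"), c("piR-1", "piR-2"),
    "piRNA"))
  # plus-strand reads TAAA TCCC GAAA -> 5'U fraction 2/3
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"), chrom = "chr1",
    start = c(150, 160, 170), end = c(154, 164, 174), strand = "+",
    sequence = c("TAAA", "TCCC", "GAAA"), length = 4L)
  asn <- assign_reads(reads, ann)
  bc <- first_base_composition(asn, biotype = "piRNA")
  expect_equal(bc$fraction[bc$base == "T"], 2 / 3)
  expect_equal(sum(bc$fraction), 1)

  # single read: one-hot
  one <- first_base_composition(asn[1, ])
  expect_equal(sort(one$fraction), c(0, 0, 0, 1))

  # minus-strand alignment: reference AAAA is read TTTT (5' end is U)
  rneg <- tibble::tibble(read_id = "n", chrom = "chr1", start = 600,
                         end = 604, strand = "-", sequence = "AAAA",
                         length = 4L)
  bcn <- first_base_composition(assign_reads(rneg, ann))
  expect_equal(bcn$fraction[bcn$base == "T"], 1)

  # generated 5'U probability is recovered within 3 binomial SEs
  ann2 <- build_tiered_annotation(generate_annotation(seed = 6)$features)
  spec <- library_spec(
    n_reads = 10000,
    tier_mixture = c(small_rna = 1, rrna = 0, other_rna = 0),
    biotype_mixture = list(small_rna = c(piRNA = 1)), seed = 13)
  sim <- generate_reads(spec, ann2)
  asn2 <- assign_reads(sim$reads, ann2)
  bc2 <- first_base_composition(asn2, biotype = "piRNA")
  expect_lt(abs(bc2$fraction[bc2$base == "T"] - 0.8),
            3 * sqrt(0.8 * 0.2 / 10000))
})

test_that("mature piRNA criteria combine size range and 5' uracil", {
  ann <- build_tiered_annotation(make_features(
    "chr1", 100, 400, "+", "piR-1", "piRNA"))
  mk <- function(len, base) tibble::tibble(
    read_id = "r", chrom = "chr1", start = 150, end = 150 + len,
    strand = "+", sequence = paste0(base, strrep("A", len - 1)),
    length = as.integer(len))
  good <- mature_pirna_fraction(assign_reads(mk(30, "T"), ann))
  expect_equal(good$joint_fraction, 1.0)
  short <- mature_pirna_fraction(assign_reads(mk(22, "T"), ann))
  expect_equal(short$joint_fraction, 0.0)
  expect_equal(short$five_prime_u_fraction, 1.0)
  # no piRNA reads: undefined marker
  expect_warning(none <- mature_pirna_fraction(
    assign_reads(mk(30, "T")[0, ], ann)), "undefined")
  expect_true(is.na(none$joint_fraction))

  # independence of the generator's draws: joint ~ 0.5 * 0.8 = 0.4
  ann2 <- build_tiered_annotation(generate_annotation(seed = 6)$features)
  spec <- library_spec(
    n_reads = 10000,
    tier_mixture = c(small_rna = 1, rrna = 0, other_rna = 0),
    biotype_mixture = list(small_rna = c(piRNA = 1)), seed = 14)
  sim <- generate_reads(spec, ann2)
  mp <- mature_pirna_fraction(assign_reads(sim$reads, ann2))
  expect_lt(abs(mp$joint_fraction - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
})

test_that("cumulative coverage sorts, accumulates and inverts correctly", {
  cc <- top_n_cumulative(c(a = 10, b = 10, c = 10, d = 10), n = 2)
  expect_equal(cc$top_n_share, 0.5)
  expect_equal(top_n_cumulative(c(only = 7), n = 1)$top_n_share, 1.0)
  expect_error(top_n_cumulative(c(a = 0, b = 0)), "zero")

  withr::with_seed(15, vals <- rlnorm(100, 0, 1.5))
  names(vals) <- sprintf("g%03d", 1:100)
  cc <- top_n_cumulative(vals, target_fraction = 0.75)
  # oracle: explicit sort and scan
  s <- sort(vals, decreasing = TRUE)
  want_n <- unname(which(cumsum(s) / sum(s) >= 0.75)[1])
  expect_equal(cc$n_for_target, want_n)
  # curve is nondecreasing and ends at 1
  expect_true(all(diff(cc$curve$cumulative) >= -1e-12))
  expect_equal(cc$curve$cumulative[100], 1)
})

test_that("profile correlation handles joins and degenerate input", {
  a <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  expect_equal(sample_correlation(a, a), 1.0)
  rev <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  fwd <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  expect_equal(sample_correlation(rev, fwd), -1.0)
  flat <- c(g1 = 1, g2 = 1, g3 = 1)
  expect_warning(r <- sample_correlation(a, flat), "zero variance")
  expect_true(is.na(r))
  expect_error(sample_correlation(c(g1 = 1), c(g1 = 2)), "at least 3")

  # union join scores absent genes as zero
  b <- c(g1 = 0.5, g4 = 0.5)
  r_union <- sample_correlation(a, b, join = "union")
  va <- c(0.5, 0.3, 0.2, 0)
  vb <- c(0.5, 0, 0, 0.5)
  expect_equal(r_union, cor(va, vb))

  # seeded bivariate sample with population r = 0.9
  withr::with_seed(16, {
    x <- rnorm(300)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(300)
  })
  r <- sample_correlation(setNames(x, sprintf("g%d", 1:300)),
                          setNames(y, sprintf("g%d", 1:300)))
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("one-minus-Pearson clustering satisfies its metric contracts", {
  withr::with_seed(17, m <- matrix(runif(5 * 40), nrow = 5,
                                   dimnames = list(sprintf("s%d", 1:5),
                                                   sprintf("g%d", 1:40))))
  # duplicated sample: distance 0 and merged first
  m2 <- rbind(m, s1copy = m["s1", ])
  hc <- hierarchical_cluster(m2)
  expect_equal(hc$distance["s1", "s1copy"], 0)
  first_merge <- sort(hc$hclust$labels[-hc$hclust$merge[1, ]])
  expect_equal(first_merge, c("s1", "s1copy"))
  # symmetry, zero diagonal, range [0, 2]
  expect_equal(hc$distance, t(hc$distance))
  expect_equal(unname(diag(hc$distance)), rep(0, 6))
  expect_true(all(hc$distance >= -1e-12 & hc$distance <= 2 + 1e-12))

  # two anti-correlated samples: distance 2
  anti <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  expect_equal(hierarchical_cluster(anti)$distance["a", "b"], 2)

  # all-zero genes are excluded before clustering
  mz <- cbind(m, dead1 = 0, dead2 = 0)
  expect_equal(hierarchical_cluster(mz)$n_genes_dropped, 2)

  # constant sample is an error naming the sample
  bad <- rbind(m, flatling = 1)
  expect_error(hierarchical_cluster(bad), "flatling")

  # template-pair design: noisy copies cluster with their templates
  withr::with_seed(18, {
    t1 <- runif(200)
    t2 <- runif(200)
    prof <- rbind(cellA = t1, evA = t1 + rnorm(200, 0, 0.02),
                  cellB = t2, evB = t2 + rnorm(200, 0, 0.02))
  })
  hc2 <- hierarchical_cluster(prof)
  groups <- stats::cutree(hc2$hclust, k = 2)
  expect_equal(groups[["cellA"]], groups[["evA"]])
  expect_equal(groups[["cellB"]], groups[["evB"]])
  expect_true(groups[["cellA"]] != groups[["cellB"]])
})
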