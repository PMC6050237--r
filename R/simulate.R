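# Synthetic study generator: annotation sets, labelled aligned reads and
# protein tables with the statistical structure the analysis assumes, so
# the whole pipeline is testable end-to-end without external data.

#' Default per-biotype read-length models
#'
#' Discrete length distributions on the 17-35 nt window. miRNA reads
#' concentrate in 20-25 nt (97% of the mass), reads from piRNA loci carry
#' half their mass in the mature 27-35 nt range, tRNA fragments are mostly
#' 30-34 nt and Y-RNA-like miscellaneous RNA fragments peak at 30-34 nt;
#' biotypes without an explicit model draw uniformly over 17-35 nt.
#'
#' @return A named list of probability vectors, names being lengths.
#' @export
default_length_models <- function() {
  list(
    miRNA = setNames(c(.01, .05, .15, .44, .24, .06, .03, .02), 19:26),
    piRNA = setNames(c(.20, .17, .13, rep(0.5 / 9, 9)), 24:35),
    tRNA = setNames(c(.05, .05, .20, .20, .20, .15, .10, .05), 28:35),
    misc_RNA = setNames(c(.10, .10, .20, .20, .20, .10, .10), 28:34)
  )
}

uniform_length_model <- function(min_len = 17L, max_len = 35L) {
  w <- min_len:max_len
  setNames(rep(1 / length(w), length(w)), w)
}

#' Specification of a synthetic small-RNA library
#'
#' Defines the generating mixture of one library: how reads distribute
#' over the three annotation tiers, over biotypes within each tier, the
#' per-biotype read-length model and the per-biotype probability that the
#' 5' base is uracil (the piRNA-like class defaults to 0.8; all other
#' biotypes draw the 5' base like any other position).
#'
#' @param n_reads Number of reads to generate.
#' @param tier_mixture Probability vector over
#'   `small_rna`/`rrna`/`other_rna` (must sum to 1).
#' @param biotype_mixture Named list of per-tier probability vectors over
#'   biotypes (each summing to 1).
#' @param length_model Named list of length distributions; see
#'   [default_length_models()].
#' @param five_prime_u_prob Named vector of per-biotype 5'-U
#'   probabilities; biotypes not listed use `default_u_prob`.
#' @param default_u_prob 5'-U probability for unlisted biotypes
#'   (default 0.25, i.e. no bias).
#' @param seed Integer seed making generation deterministic.
#' @return A `library_spec` object.
#' @export
library_spec <- function(n_reads, tier_mixture, biotype_mixture,
                         length_model = default_length_models(),
                         five_prime_u_prob = c(piRNA = 0.8),
                         default_u_prob = 0.25, seed = 1L) {
  if (!is.numeric(n_reads) || n_reads < 1) {
    abort("`n_reads` must be a positive integer")
  }
  check_mixture <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("%s must be a probability vector summing to 1", what))
    }
  }
  if (!setequal(names(tier_mixture), TIER_ORDER)) {
    abort("`tier_mixture` must be named over small_rna/rrna/other_rna")
  }
  check_mixture(tier_mixture, "`tier_mixture`")
  for (t in names(biotype_mixture)) {
    check_mixture(biotype_mixture[[t]], sprintf("`biotype_mixture$%s`", t))
  }
  for (b in names(length_model)) {
    check_mixture(length_model[[b]], sprintf("`length_model$%s`", b))
  }
  structure(
    list(n_reads = as.integer(n_reads),
         tier_mixture = tier_mixture[TIER_ORDER],
         biotype_mixture = biotype_mixture,
         length_model = length_model,
         five_prime_u_prob = five_prime_u_prob,
         default_u_prob = default_u_prob,
         seed = as.integer(seed)),
    class = "library_spec"
  )
}

#' Library presets mirroring parental cells and EVs
#'
#' Two named presets: `preset_cell_like()` reflects a parental-cell
#' library (tier mixture 0.80/0.08/0.12, miRNA-dominated small-RNA tier),
#' `preset_ev_like()` an extracellular-vesicle library (0.22/0.60/0.18,
#' rRNA-fragment-dominated, piRNA-rich small-RNA tier, tRNA-fragment-rich
#' other-RNA tier with mitochondrial rRNA practically absent).
#'
#' @param n_reads Number of reads (default 50000).
#' @param seed Integer seed.
#' @return A `library_spec`.
#' @export
preset_cell_like <- function(n_reads = 50000L, seed = 1L) {
  library_spec(
    n_reads = n_reads,
    tier_mixture = c(small_rna = 0.80, rrna = 0.08, other_rna = 0.12),
    biotype_mixture = list(
      small_rna = c(miRNA = 0.77, piRNA = 0.03, snRNA = 0.12, snoRNA = 0.08),
      rrna = c(rRNA_LSU = 0.60, rRNA_SSU = 0.30, Mt_rRNA = 0.10),
      other_rna = c(tRNA = 0.30, protein_coding = 0.35, misc_RNA = 0.15,
                    lncRNA = 0.10, processed_transcript = 0.05,
                    pseudogene = 0.05)
    ),
    seed = seed
  )
}

#' @rdname preset_cell_like
#' @export
preset_ev_like <- function(n_reads = 50000L, seed = 1L) {
  library_spec(
    n_reads = n_reads,
    tier_mixture = c(small_rna = 0.22, rrna = 0.60, other_rna = 0.18),
    biotype_mixture = list(
      small_rna = c(miRNA = 0.25, piRNA = 0.33, snRNA = 0.22, snoRNA = 0.20),
      rrna = c(rRNA_LSU = 0.60, rRNA_SSU = 0.398, Mt_rRNA = 0.002),
      other_rna = c(tRNA = 0.45, misc_RNA = 0.25, protein_coding = 0.20,
                    lncRNA = 0.05, pseudogene = 0.05)
    ),
    seed = seed
  )
}

#' Default locus counts of the synthetic annotation
#' @return Named integer vector of loci per biotype.
#' @export
default_locus_counts <- function() {
  c(miRNA = 60L, piRNA = 40L, snRNA = 20L, snoRNA = 20L,
    rRNA_LSU = 12L, rRNA_SSU = 10L, Mt_rRNA = 4L,
    tRNA = 48L, protein_coding = 40L, misc_RNA = 20L, lncRNA = 15L,
    processed_transcript = 10L, pseudogene = 10L)
}

locus_length_for <- function(biotype) {
  lens <- c(miRNA = 80L, piRNA = 60L, snRNA = 150L, snoRNA = 120L,
            rRNA_LSU = 160L, rRNA_SSU = 160L, Mt_rRNA = 160L,
            tRNA = 140L, Mt_tRNA = 140L)
  unname(ifelse(is.na(lens[biotype]), 200L, lens[biotype]))
}

TRNA_FAMILIES <- c("Gly-GCC", "Glu-CTC", "His-GTG", "Lys-CTT", "Asp-GTC",
                   "Val-AAC")

#' Generate a synthetic annotation set with known structure
#'
#' Places non-overlapping loci of each biotype over a toy genome, except
#' for a requested fraction of piRNA loci deliberately nested inside tRNA
#' loci on the same strand (to exercise cross-biotype ambiguity masked by
#' the cascade). rRNA loci are additionally emitted a second time under a
#' separate source tag with identical coordinates, emulating two redundant
#' rRNA annotation sources that the reciprocal-overlap filter must
#' deduplicate. tRNA gene ids follow the `tRNA-<AA>-<anticodon>-<locus>`
#' pattern across six isoacceptor families. Generation is deterministic
#' given the seed, and with a directory argument the set is also written
#' as GTF (gene-model biotypes), BED6 (tRNA) and a duplicate-source rRNA
#' GTF.
#'
#' @param locus_counts Named integer vector of loci per biotype.
#' @param genome Named vector of chromosome lengths.
#' @param overlap_fraction Fraction of piRNA loci nested inside tRNA loci.
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return A list with `features` (the primary feature tibble),
#'   `rrna_duplicates` (the redundant rRNA source), `truth` (including the
#'   piRNA-tRNA `overlaps` table) and `paths` (when written).
#' @export
generate_annotation <- function(locus_counts = default_locus_counts(),
                                genome = c(chr1 = 2000000L, chr2 = 2000000L),
                                overlap_fraction = 0, seed = 1L, dir = NULL) {
  check_fraction(overlap_fraction, "overlap_fraction", closed_left = TRUE)
  n_pirna <- locus_counts[["piRNA"]] %||% 0L
  n_trna <- locus_counts[["tRNA"]] %||% 0L
  n_nested <- as.integer(round(overlap_fraction * n_pirna))
  if (n_nested > n_trna) {
    abort("not enough tRNA loci to host the requested overlapping piRNA loci")
  }
  withr::with_seed(seed, {
    biotype <- rep(names(locus_counts), locus_counts)
    ids <- unlist(lapply(names(locus_counts), function(b) {
      k <- locus_counts[[b]]
      if (b == "tRNA") {
        fam <- rep_len(TRNA_FAMILIES, k)
        within <- as.integer(stats::ave(seq_len(k), fam, FUN = seq_along))
        sprintf("tRNA-%s-%d", fam, within)
      } else {
        sprintf("%s-%04d", b, seq_len(k))
      }
    }))
    lens <- locus_length_for(biotype)
    # which piRNA loci are nested (the first n_nested of them)
    pirna_rows <- which(biotype == "piRNA")
    nested_rows <- pirna_rows[seq_len(n_nested)]
    trna_rows <- which(biotype == "tRNA")
    host_rows <- trna_rows[seq_len(n_nested)]
    free <- setdiff(seq_along(biotype), nested_rows)
    # shuffle placement order of the independent loci, then lay them out
    # sequentially with random gaps, round-robin over chromosomes
    ord <- sample(free)
    chrom <- character(length(biotype))
    start <- integer(length(biotype))
    chrom_names <- names(genome)
    cursor <- setNames(rep(1000L, length(genome)), chrom_names)
    ci <- 0L
    for (i in ord) {
      ci <- ci %% length(genome) + 1L
      cn <- chrom_names[ci]
      gap <- sample(50:500, 1)
      pos <- cursor[[cn]] + gap
      if (pos + lens[i] > genome[[cn]] - 1000L) {
        abort(sprintf("genome too small for the requested loci (chromosome %s)",
                      cn))
      }
      chrom[i] <- cn
      start[i] <- pos
      cursor[[cn]] <- pos + lens[i]
    }
    strand <- sample(c("+", "-"), length(biotype), replace = TRUE)
    # nest the designated piRNA loci inside their tRNA hosts, same strand
    for (j in seq_len(n_nested)) {
      p <- nested_rows[j]
      h <- host_rows[j]
      chrom[p] <- chrom[h]
      start[p] <- start[h] + 20L
      strand[p] <- strand[h]
    }
    features <- tibble::tibble(
      chrom = chrom, start = start, end = start + lens, strand = strand,
      gene_id = ids, gene_name = ids, biotype = biotype,
      source = ifelse(biotype == "tRNA", "ucsc_trna_like", "ensembl_like")
    )
    is_rrna <- features$biotype %in% c("rRNA_LSU", "rRNA_SSU")
    rrna_dup <- dplyr::mutate(features[is_rrna, , drop = FALSE],
                              source = "repeatmasker_like")
    overlaps <- tibble::tibble(
      pirna_gene_id = ids[nested_rows],
      trna_gene_id = ids[host_rows]
    )
  })
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gtf_path <- file.path(dir, "annotation.gtf")
    bed_path <- file.path(dir, "trna.bed")
    dup_path <- file.path(dir, "rrna_duplicate_source.gtf")
    main <- features[features$biotype != "tRNA", , drop = FALSE]
    write_gtf(main, gtf_path)
    write_bed6(features[features$biotype == "tRNA", , drop = FALSE], bed_path)
    write_gtf(rrna_dup, dup_path)
    paths <- list(gtf = gtf_path, trna_bed = bed_path, rrna_duplicate = dup_path)
  }
  list(features = features, rrna_duplicates = rrna_dup,
       truth = list(loci = features, overlaps = overlaps), paths = paths)
}

write_gtf <- function(features, path) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   features$gene_id, features$gene_name, features$biotype)
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, features$source, features$start + 1L,
                   features$end, features$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

write_bed6 <- function(features, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", features$chrom, features$start,
                   features$end, features$gene_id, features$strand)
  writeLines(lines, path)
  invisible(path)
}

# one random ACGT string per requested length (vectorised)
random_strings <- function(lens) {
  total <- sum(lens)
  if (total == 0) {
    return(rep("", length(lens)))
  }
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  idx <- factor(rep.int(seq_along(lens), lens), levels = seq_along(lens))
  vapply(split(chars, idx), paste, "", collapse = "")
}

#' Generate labelled aligned reads from a library specification
#'
#' Each read is drawn hierarchically: tier from the tier mixture, biotype
#' from the tier's biotype mixture, locus uniformly among that biotype's
#' loci, length from the biotype's length model, start uniformly within
#' the locus so the read fits, and a 5' uracil with the biotype's 5'-U
#' probability (otherwise the first base is uniform over A/C/G; remaining
#' bases are i.i.d. uniform over ACGT). Reads are emitted already aligned
#' — the SAM file is the ground truth of placement — with a parallel FASTQ
#' carrying the 3' adapter and a random tail truncated at the sequencing
#' cycle count, for exercising the preprocessing stage.
#'
#' @param spec A [library_spec()].
#' @param annotation A feature tibble or `tiered_annotation`; every
#'   biotype with positive mixture mass must have at least one locus.
#' @param dir Optional directory; writes `reads.sam`, `reads.fastq` and
#'   `truth.tsv`.
#' @param adapter 3' adapter appended in the FASTQ output.
#' @param cycles Sequencing cycle count truncating the FASTQ reads
#'   (default 51).
#' @param genome Optional named chromosome lengths for the SAM header.
#' @return A list with `reads` (aligned-read tibble as [read_sam()] would
#'   return), `truth` (per-read tibble with the generating labels) and
#'   `paths` (when written).
#' @export
generate_reads <- function(spec, annotation, dir = NULL,
                           adapter = "AGATCGGAAGAGCACACGTCT", cycles = 51L,
                           genome = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  features <- if (inherits(annotation, "tiered_annotation"))
    annotation$features else annotation
  config <- if (inherits(annotation, "tiered_annotation"))
    annotation$config else build_tier_config()
  n <- spec$n_reads
  loci_by_biotype <- split(seq_len(nrow(features)), features$biotype)
  withr::with_seed(spec$seed, {
    tier <- sample(names(spec$tier_mixture), n, replace = TRUE,
                   prob = spec$tier_mixture)
    biotype <- character(n)
    for (t in TIER_ORDER) {
      idx <- which(tier == t)
      if (length(idx) == 0) next
      mix <- spec$biotype_mixture[[t]]
      if (is.null(mix)) {
        abort(sprintf("tier '%s' has mixture mass but no biotype mixture", t))
      }
      biotype[idx] <- sample(names(mix), length(idx), replace = TRUE,
                             prob = mix)
    }
    used <- unique(biotype)
    no_loci <- setdiff(used, names(loci_by_biotype))
    if (length(no_loci) > 0) {
      abort(sprintf("biotype(s) with mixture mass but zero loci: %s",
                    paste(no_loci, collapse = ", ")))
    }
    locus <- integer(n)
    len <- integer(n)
    for (b in used) {
      idx <- which(biotype == b)
      locus[idx] <- sample(loci_by_biotype[[b]], length(idx), replace = TRUE)
      model <- spec$length_model[[b]] %||% uniform_length_model()
      len[idx] <- as.integer(sample(names(model), length(idx),
                                    replace = TRUE, prob = model))
    }
    span <- features$end[locus] - features$start[locus]
    offset <- floor(runif(n) * (span - len + 1))
    start <- features$start[locus] + as.integer(offset)
    strand <- features$strand[locus]
    u_prob <- unname(
      ifelse(is.na(spec$five_prime_u_prob[biotype]),
             spec$default_u_prob, spec$five_prime_u_prob[biotype]))
    is_u <- runif(n) < u_prob
    first <- ifelse(is_u, "T", sample(c("A", "C", "G"), n, replace = TRUE))
    rest <- random_strings(len - 1L)
    read_seq <- paste0(first, rest)
    read_id <- sprintf("read%07d", seq_len(n))
    ref_seq <- read_seq
    neg <- strand == "-"
    if (any(neg)) {
      ref_seq[neg] <- reverse_complement(read_seq[neg])
    }
    tail_len <- pmax(0L, cycles - len - nchar(adapter))
    fastq_seq <- substr(paste0(read_seq, adapter, random_strings(tail_len)),
                        1L, cycles)
  })
  reads <- tibble::tibble(
    read_id = read_id, chrom = features$chrom[locus], start = start,
    end = start + len, strand = strand, sequence = ref_seq, length = len
  )
  truth <- tibble::tibble(
    read_id = read_id, gene_id = features$gene_id[locus],
    biotype = biotype, tier = unname(config[biotype]), length = len,
    first_base = first, chrom = features$chrom[locus], start = start,
    end = start + len, strand = strand
  )
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sam_path <- file.path(dir, "reads.sam")
    fastq_path <- file.path(dir, "reads.fastq")
    truth_path <- file.path(dir, "truth.tsv")
    write_sam(reads, sam_path, genome = genome)
    write_fastq(tibble::tibble(read_id = read_id, sequence = fastq_seq,
                               quality = strrep("I", nchar(fastq_seq))),
                fastq_path)
    readr::write_tsv(truth, truth_path)
    paths <- list(sam = sam_path, fastq = fastq_path, truth = truth_path)
  }
  list(reads = reads, truth = truth,
       fastq = tibble::tibble(read_id = read_id, sequence = fastq_seq),
       paths = paths)
}

#' Generate a synthetic protein abundance table
#'
#' Protein MS-Area abundances are drawn log-normally — reproducing the
#' heavy-tailed structure in which a low number of highly abundant
#' proteins accounts for most of the protein mass — and each protein's
#' membership in each term set is an independent Bernoulli draw with the
#' stated probability.
#'
#' @param n Number of proteins.
#' @param meanlog,sdlog Log-normal parameters (`sdlog = 0` gives equal
#'   abundances).
#' @param set_probs Named vector of membership probabilities per term set.
#' @param seed Integer seed.
#' @param dir Optional directory; writes `proteins.tsv` and
#'   `annotations.tsv`.
#' @return A list with `proteins` (tibble `protein_id`, `ms_area`),
#'   `annotations` (tibble `protein_id`, `term`), `term_sets` (a list of
#'   [go_term_set()] objects) and `truth` (the membership matrix).
#' @export
generate_protein_table <- function(n, meanlog = 0, sdlog = 2,
                                   set_probs = c(rna_binding = 0.21,
                                                 mirna_related = 0.01),
                                   seed = 1L, dir = NULL) {
  if (n < 1) abort("`n` must be positive")
  if (sdlog < 0) abort("`sdlog` must be non-negative")
  if (any(set_probs < 0 | set_probs > 1)) {
    abort("`set_probs` must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    proteins <- tibble::tibble(
      protein_id = sprintf("P%05d", seq_len(n)),
      ms_area = stats::rlnorm(n, meanlog, sdlog)
    )
    membership <- vapply(set_probs, function(p)
      stats::runif(n) < p, logical(n))
    membership <- matrix(membership, nrow = n,
                         dimnames = list(NULL, names(set_probs)))
  })
  annotations <- purrr::map_dfr(names(set_probs), function(s) {
    tibble::tibble(protein_id = proteins$protein_id[membership[, s]],
                   term = s)
  })
  term_sets <- lapply(names(set_probs), function(s) {
    go_term_set(s, term_ids = s,
                protein_ids = proteins$protein_id[membership[, s]])
  })
  names(term_sets) <- names(set_probs)
  truth <- dplyr::bind_cols(tibble::tibble(protein_id = proteins$protein_id),
                            tibble::as_tibble(membership))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ppath <- file.path(dir, "proteins.tsv")
    apath <- file.path(dir, "annotations.tsv")
    readr::write_tsv(proteins, ppath)
    readr::write_tsv(annotations, apath)
    paths <- list(proteins = ppath, annotations = apath)
  }
  list(proteins = proteins, annotations = annotations, term_sets = term_sets,
       truth = truth, paths = paths)
}
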