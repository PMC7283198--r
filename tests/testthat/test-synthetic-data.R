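# The toy-genome and read simulator: determinism, designed structure,
# truth-table bookkeeping, error model.

test_that("the generator is deterministic for a fixed seed", {
  a <- generate_genome(genome_spec(n_genes = 12L, seed = 5L))
  b <- generate_genome(genome_spec(n_genes = 12L, seed = 5L))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$genes), as.character(b$genes))
  c_ <- generate_genome(genome_spec(n_genes = 12L, seed = 6L))
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))

  sim1 <- simulate_reads(a, read_sim_spec(reads_per_transcript = 3L, seed = 9L))
  sim2 <- simulate_reads(a, read_sim_spec(reads_per_transcript = 3L, seed = 9L))
  expect_identical(as.character(sim1$reads), as.character(sim2$reads))
  expect_identical(sim1$truth, sim2$truth)
})

test_that("pair fractions produce the designed gene counts", {
  tg <- generate_genome(genome_spec(n_genes = 20L,
                                    fraction_antisense_pairs = 0.2,
                                    seed = 13L))
  mc <- S4Vectors::mcols(tg$genes)
  expect_equal(sum(mc$pair_type %in% c("antisense_host", "antisense_partner")),
               4L)
  expect_equal(sum(mc$pair_type == "antisense_host"),
               sum(mc$pair_type == "antisense_partner"))
  # spliced genes carry exactly two exons and a designed minor chain
  for (g in mc$gene_id[mc$spliced]) {
    expect_length(tg$exons[[g]], 2L)
    expect_length(tg$minor_exons[[g]], 2L)
    expect_false(identical(as.character(tg$exons[[g]]),
                           as.character(tg$minor_exons[[g]])))
  }
})

test_that("unrelated loci respect the intergenic gap; designed pairs overlap", {
  tg <- generate_genome(genome_spec(seed = 14L))
  mc <- S4Vectors::mcols(tg$genes)
  for (chrom in unique(as.character(seqnames(tg$genes)))) {
    sel <- as.character(seqnames(tg$genes)) == chrom
    g <- tg$genes[sel]
    pt <- mc$pair_type[sel]
    o <- order(start(g))
    gaps <- start(g)[o][-1] - cummax(end(g)[o])[-sum(sel)] - 1L
    paired <- (pt[o][-1] != "single") & (pt[o][-sum(sel)] != "single")
    expect_true(all(gaps[!paired] >= tg$spec$intergenic_min_gap))
  }
  # designed overlapping pairs exist on both pair classes
  expect_true(any(mc$pair_type == "antisense_partner"))
  expect_true(any(mc$pair_type == "tandem"))
})

test_that("every read has exactly one truth row and true alignment", {
  x <- std_sim()
  expect_equal(nrow(x$sim$truth), length(x$sim$reads))
  expect_identical(x$sim$truth$read_id, names(x$sim$reads))
  expect_identical(names(x$sim$alignments), names(x$sim$reads))
  # perfect alignments span the truth interval on the truth strand
  sp <- unlist(range(x$sim$alignments))
  expect_equal(start(sp), x$sim$truth$span_start)
  expect_equal(end(sp), x$sim$truth$span_end)
  expect_equal(as.character(strand(sp)), x$sim$truth$strand)
})

test_that("error-free reads reproduce flank + transcript + tail exactly", {
  tg <- generate_genome(genome_spec(n_genes = 8L, seed = 15L))
  spec <- read_sim_spec(reads_per_transcript = 4L, seed = 16L)
  sim <- simulate_reads(tg, spec)
  tt <- sim$truth
  for (i in seq_len(6L)) {
    ex <- if (tt$chain[i] == "minor") tg$minor_exons[[tt$gene_id[i]]] else
      tg$exons[[tt$gene_id[i]]]
    body <- genome_correct(ex, tg$genome)
    r <- as.character(sim$reads[[i]])
    if (tt$orientation[i] == "antisense") {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    expect_true(startsWith(r, paste0(spec$flank, body)))
    tail_part <- substring(r, nchar(spec$flank) + nchar(body) + 1L)
    if (tt$has_tail[i]) {
      expect_match(tail_part, "^A+$")
      expect_gte(nchar(tail_part), 12L)
    } else {
      expect_equal(tail_part, "")
    }
  }
})

test_that("read length reflects the indel-balanced error model", {
  tg <- generate_genome(genome_spec(n_genes = 6L, seed = 17L))
  e <- 0.12
  sim0 <- simulate_reads(tg, read_sim_spec(reads_per_transcript = 6L,
                                           error_rate = 0, seed = 18L))
  sim1 <- simulate_reads(tg, read_sim_spec(reads_per_transcript = 6L,
                                           error_rate = e, seed = 18L))
  n0 <- sum(Biostrings::width(sim0$reads))
  n1 <- sum(Biostrings::width(sim1$reads))
  # deletions and insertions occur at the same rate, so total length is
  # conserved in expectation; allow 3 sd of the net indel noise
  sd_len <- sqrt(2 * n0 * e / 3)
  expect_lt(abs(n1 - n0), 3 * sd_len + 1)
  # and reads are no longer identical to their error-free versions
  expect_false(identical(as.character(sim1$reads[[1]]),
                         as.character(sim0$reads[[1]])))
})

test_that("tail truncation drives the discard fraction", {
  tg <- generate_genome(genome_spec(n_genes = 10L, seed = 19L))
  q <- 0.25
  sim <- simulate_reads(tg, read_sim_spec(reads_per_transcript = 20L,
                                          tail_truncation_prob = q,
                                          seed = 20L))
  frac <- mean(!sim$truth$has_tail)
  n <- nrow(sim$truth)
  expect_lt(abs(frac - q), 1.96 * sqrt(q * (1 - q) / n))
})

test_that("written genome, annotation and reads round-trip from disk", {
  tg <- generate_genome(genome_spec(n_genes = 8L, seed = 23L))
  sim <- simulate_reads(tg, read_sim_spec(reads_per_transcript = 3L, seed = 24L))
  dir <- tempfile()
  gp <- write_genome(tg, dir)
  rp <- write_sim_reads(sim, dir)
  g2 <- Biostrings::readDNAStringSet(gp[["fasta"]])
  names(g2) <- sub("\\s.*$", "", names(g2))
  expect_identical(as.character(g2), as.character(tg$genome))
  ann <- read_annotation(gp[["gff3"]])
  expect_identical(S4Vectors::mcols(ann$genes)$gene_id,
                   S4Vectors::mcols(tg$genes)$gene_id)
  expect_identical(ranges(ann$genes), ranges(tg$genes))
  fq <- read_fastq(rp[["fastq"]])
  expect_identical(as.character(fq), as.character(as(sim$reads, "DNAStringSet")))
  bed <- load_alignments(rp[["bed"]])
  expect_equal(length(bed$blocks), length(sim$alignments))
})
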