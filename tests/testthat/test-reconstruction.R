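# Unit segmentation, end-site clustering, unit splitting, intron-chain
# collapsing, model building and classification.

test_that("segment_units records maximal runs strictly above threshold", {
  expect_equal(as.data.frame(ranges(segment_units(c(0, 0, 3, 3, 3, 0, 0), 2L)))[, 1:2],
               data.frame(start = 3L, end = 5L))
  expect_length(segment_units(rep(0, 50), 2L), 0L)
  u <- segment_units(c(3, 3, 1, 3, 3), 2L)
  expect_equal(start(u), c(1L, 4L))
  expect_equal(end(u), c(2L, 5L))
  # depth equal to the threshold does not open a unit: "exceeds" is strict
  expect_length(segment_units(rep(2, 10), 2L), 0L)
})

test_that("segment_units matches the brute-force scan on random tracks", {
  set.seed(101)
  for (rep_i in 1:300) {
    n <- sample(c(5:200, 5000), 1)
    depth <- sample(0:6, n, replace = TRUE)
    thr <- sample(1:4, 1)
    u <- segment_units(depth, thr)
    b <- brute_segment(depth, thr)
    expect_equal(start(u), unname(b[, 1]))
    expect_equal(end(u), unname(b[, 2]))
  }
})

test_that("unit base total is non-increasing in the threshold", {
  set.seed(102)
  depth <- sample(0:8, 2000, replace = TRUE)
  widths <- vapply(1:7, function(thr) {
    sum(width(segment_units(depth, thr)))
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("cluster_sites gap-links positions and picks modal representative", {
  cl <- cluster_sites(c(`100` = 5L, `101` = 3L, `130` = 2L), 10L)
  expect_equal(cl$representative, c(100L, 130L))
  expect_equal(cl$total_count, c(8L, 2L))
  one <- cluster_sites(c(`42` = 1L), 5L)
  expect_equal(one$representative, 42L)
  expect_equal(nrow(cluster_sites(setNames(integer(0), character(0)), 5L)), 0L)
  # ties break 5'-most on the strand
  tie <- c(`10` = 4L, `12` = 4L)
  expect_equal(cluster_sites(tie, 5L, strand = "+")$representative, 10L)
  expect_equal(cluster_sites(tie, 5L, strand = "-")$representative, 12L)
})

test_that("cluster_sites matches the brute-force linkage on random inputs", {
  set.seed(103)
  for (rep_i in 1:300) {
    n <- sample(1:60, 1)
    pos <- sort(sample(1:500, n))
    counts <- setNames(sample(1:9, n, replace = TRUE), pos)
    gap <- sample(0:30, 1)
    got <- cluster_sites(counts, gap)
    want <- brute_cluster(counts, gap)
    expect_equal(got$representative, want$representative)
    expect_equal(got$total_count, unname(want$total_count))
  }
})

test_that("split_unit cuts at a strong internal 3' cluster", {
  # 12 reads end at 481 (internal 3' cluster), 11 start at 501
  members <- aln_set("c", "+", c(
    replicate(12, cbind(1, 481), simplify = FALSE),
    replicate(11, cbind(501, 1000), simplify = FALSE)))
  unit <- GRanges("c", IRanges(1, 1000), strand = "+")
  genes <- split_unit(unit, members, cluster_gap = 20L,
                      min_site_count = 5L, min_gene_len = 50L)
  expect_equal(start(genes), c(1L, 501L))
  expect_equal(end(genes), c(481L, 1000L))
})

test_that("split_unit leaves units without qualifying clusters intact", {
  unit <- GRanges("c", IRanges(1, 1000), strand = "+")
  members <- aln_set("c", "+", replicate(8, cbind(1, 1000), simplify = FALSE))
  expect_equal(as.character(split_unit(unit, members)), as.character(unit))
  # internal cluster below min_site_count does not cut
  weak <- aln_set("c", "+", c(
    replicate(2, cbind(1, 481), simplify = FALSE),
    replicate(8, cbind(1, 1000), simplify = FALSE)))
  expect_length(split_unit(unit, weak, min_site_count = 5L), 1L)
})

test_that("split_unit mirrors on the minus strand", {
  # '-' transcription right to left: 3' sites at low coordinates
  members <- aln_set("c", "-", c(
    replicate(12, cbind(520, 1000), simplify = FALSE),
    replicate(11, cbind(1, 500), simplify = FALSE)))
  unit <- GRanges("c", IRanges(1, 1000), strand = "-")
  genes <- split_unit(unit, members)
  # upstream gene (in transcription order) is the right piece, ending (3')
  # at the internal cluster representative 520; next gene starts at the
  # strongest 5' site below the cut (500)
  expect_equal(start(genes), c(1L, 520L))
  expect_equal(end(genes), c(500L, 1000L))
})

test_that("collapse_spliced groups by exact intron-chain identity", {
  grl <- aln_set("c", "+", list(
    rbind(c(1, 100), c(201, 300)),
    rbind(c(5, 100), c(201, 290)),
    rbind(c(1, 100), c(202, 300)),
    cbind(1, 300)))
  got <- collapse_spliced(grl)
  expect_equal(nrow(got), 2L)                 # single-block read excluded
  expect_equal(got$support[1], 2L)            # identical introns collapse
  expect_setequal(got$support, c(2L, 1L))     # shifted acceptor separates
  expect_equal(sort(unname(unlist(got$read_ids))), c("r001", "r002", "r003"))
})

test_that("collapse_spliced matches brute-force key grouping", {
  set.seed(104)
  for (rep_i in 1:100) {
    n <- sample(2:8, 1)
    block_list <- replicate(n, {
      k <- sample(1:3, 1)
      bounds <- sort(sample(seq(1, 900, by = 10), 2 * k))
      cbind(bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)])
    }, simplify = FALSE)
    got <- collapse_spliced(aln_set("c", "+", block_list))
    want <- brute_collapse(block_list)
    expect_equal(nrow(got), length(want))
    expect_equal(sort(got$support), sort(unname(as.integer(want))))
  }
})

test_that("build_models emits monoexonic or major-chain models", {
  cfg <- default_config()
  # no spliced reads: model = the interval
  iv <- GRanges("c", IRanges(1, 500), strand = "+")
  mono <- aln_set("c", "+", replicate(6, cbind(1, 500), simplify = FALSE))
  bm <- build_models(iv, mono, config = cfg)
  expect_length(bm$models, 1L)
  expect_length(S4Vectors::mcols(bm$models)$exons[[1]], 1L)

  # 90% of reads share one chain: its exons become the model
  spliced <- aln_set("c", "+", c(
    replicate(9, rbind(c(1, 200), c(301, 500)), simplify = FALSE),
    replicate(1, rbind(c(1, 200), c(311, 500)), simplify = FALSE)))
  ivs <- GRanges("c", IRanges(c(1, 301), c(200, 500)), strand = "+")
  bm <- build_models(ivs, spliced, config = cfg)
  expect_length(bm$models, 1L)
  ex <- S4Vectors::mcols(bm$models)$exons[[1]]
  expect_equal(start(ex), c(1L, 301L))
  expect_equal(end(ex), c(200L, 500L))

  # two split genes give two non-overlapping models
  two <- GRanges("c", IRanges(c(1, 501), c(481, 1000)), strand = "+")
  members <- aln_set("c", "+", c(
    replicate(5, cbind(1, 481), simplify = FALSE),
    replicate(5, cbind(501, 1000), simplify = FALSE)))
  bm <- build_models(two, members, config = cfg)
  expect_length(bm$models, 2L)
  expect_length(GenomicRanges::findOverlaps(bm$models[1], bm$models[2]), 0L)
})

test_that("classify_models labels ORF overlap, antisense and intergenic", {
  genes <- GRanges("c", IRanges(c(201, 2001), c(800, 2600)),
                   strand = c("+", "-"))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"), orf_start = c(261, 2081),
    orf_end = c(720, 2520), spliced = FALSE)
  ann <- list(genes = genes)
  mk <- function(s, e, st) {
    m <- GRanges("c", IRanges(s, e), strand = st)
    S4Vectors::mcols(m) <- S4Vectors::DataFrame(
      transcript_id = "t", support = 5L, class_label = "UNSET",
      exons = GenomicRanges::GRangesList(GRanges("c", IRanges(s, e), strand = st)))
    m
  }
  got <- classify_models(mk(101, 500, "+"), ann)
  expect_equal(S4Vectors::mcols(got)$class_label, "ORF_OVERLAP")
  got <- classify_models(mk(101, 500, "-"), ann)
  expect_equal(S4Vectors::mcols(got)$class_label, "ANTISENSE")
  # gene desert between gA (+, pointing right) and gB (-, pointing left):
  # both neighbours transcribe toward the model
  got <- classify_models(mk(1200, 1600, "+"), ann)
  expect_equal(S4Vectors::mcols(got)$class_label, "INTERGENIC")
  expect_equal(S4Vectors::mcols(got)$sub_label, "convergent")
})

test_that("antisense reads never change sense-strand models", {
  x <- std_sim()
  sr <- strand_reads(x$sim$reads)
  alns <- x$sim$alignments[names(x$sim$alignments) %in% names(sr$reads)]
  sp <- unlist(range(alns))
  plus_only <- alns[as.character(strand(sp)) == "+"]
  m_all <- reconstruct_transcripts(alns, x$tg$genome)
  m_plus <- reconstruct_transcripts(plus_only, x$tg$genome)
  sel <- as.character(strand(m_all$models)) == "+"
  expect_equal(as.character(m_all$models[sel]), as.character(m_plus$models))
})
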