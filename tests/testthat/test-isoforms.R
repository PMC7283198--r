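# Isoform filtering, major selection, ORF/uORF and UTR isoform calling.

iso_df <- function(supports, donors = NULL) {
  df <- data.frame(chain = sprintf("chain%02d", seq_along(supports)),
                   support = as.integer(supports),
                   stringsAsFactors = FALSE)
  if (is.null(donors)) donors <- 100L + 10L * seq_along(supports)
  df$introns <- lapply(donors, function(d) {
    GRanges("c", IRanges(d, d + 100L), strand = "+")
  })
  df
}

test_that("filter_isoforms applies the >1 read and 1/10-coverage rules", {
  got <- filter_isoforms(iso_df(c(1, 3, 10)), locus_coverage = 50L)
  expect_equal(got$support, c(10L, 3L, 1L))     # ordered by support
  expect_equal(got$kept, c(TRUE, FALSE, FALSE)) # 3 < 50/10, 1 < 2 reads
  cnt <- attr(got, "counts")
  expect_equal(unname(cnt["detected"]), unname(cnt["filtered"] + cnt["kept"]))
})

test_that("filter_isoforms is idempotent and monotone in coverage", {
  df <- iso_df(c(2, 5, 9, 40))
  once <- filter_isoforms(df, 80L)
  twice <- filter_isoforms(once[, names(df)], 80L)
  expect_equal(once$kept, twice$kept)
  kept_n <- vapply(c(40L, 80L, 200L, 400L, 800L), function(cov) {
    sum(filter_isoforms(df, cov)$kept)
  }, integer(1))
  expect_true(all(diff(kept_n) <= 0))
})

test_that("minor isoforms below a tenth of coverage are always filtered", {
  # paper-shape sanity on the simulator's designed minor chain
  tg <- generate_genome(genome_spec(n_genes = 10L, seed = 51L))
  sim <- simulate_reads(tg, read_sim_spec(reads_per_transcript = 40L,
                                          minor_isoform_fraction = 0.05,
                                          seed = 52L))
  tt <- sim$truth
  for (g in unique(tt$gene_id[tt$chain != "mono"])) {
    reads <- tt[tt$gene_id == g, ]
    groups <- collapse_spliced(sim$alignments[reads$read_id])
    got <- filter_isoforms(groups, locus_coverage = nrow(reads))
    minor_support <- sum(reads$chain == "minor")
    minor_kept <- got$kept[got$support == minor_support & got$chain %in%
                             reads$intron_chain[reads$chain == "minor"]]
    if (minor_support < max(2L, nrow(reads) / 10)) {
      expect_false(any(minor_kept))
    }
  }
})

test_that("remove_polyA_exons removes short terminal poly(A) exons only", {
  a14 <- paste0(strrep("A", 7), "C", strrep("A", 7))  # 15 nt, 14/15 A
  genome <- Biostrings::DNAStringSet(c(
    g = paste0(strrep("GC", 100), a14, strrep("GC", 100),
               strrep("A", 15), strrep("GC", 100))))
  # layout: [1,200] GC, [201,215] A-rich, [216,415] GC, [416,430] all A,
  # [431,630] GC
  chain <- GRanges("g", IRanges(c(1, 201), c(200, 215)), strand = "+")
  got <- remove_polyA_exons(chain, genome)
  expect_equal(as.character(got), "g:1-200:+")

  mixed <- GRanges("g", IRanges(c(1, 216), c(200, 230)), strand = "+")
  expect_length(remove_polyA_exons(mixed, genome), 2L)

  interior <- GRanges("g", IRanges(c(1, 416, 431), c(200, 430, 630)),
                      strand = "+")
  expect_length(remove_polyA_exons(interior, genome), 3L)

  # on the minus strand the tail shows as poly(T) on the reference
  t14 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a14)))
  genome2 <- Biostrings::DNAStringSet(c(g = paste0(t14, strrep("GC", 100))))
  chain2 <- GRanges("g", IRanges(c(1, 16), c(15, 215)), strand = "-")
  expect_equal(as.character(remove_polyA_exons(chain2, genome2)), "g:16-215:-")
})

test_that("select_major prefers support then the 5'-most splice sites", {
  df <- iso_df(c(10, 3))
  expect_equal(select_major(df)$major$chain, "chain01")
  tie <- iso_df(c(5, 5), donors = c(102L, 100L))
  expect_equal(select_major(tie)$major$chain, "chain02")  # donor 100 wins
  single <- iso_df(7)
  sel <- select_major(single)
  expect_equal(sel$major$chain, "chain01")
  expect_equal(nrow(sel$minors), 0L)
  expect_error(select_major(iso_df(integer(0))), "empty")
})

test_that("find_longest_orf scans three frames with strict length cutoff", {
  expect_null(find_longest_orf("ATGTAA"))              # 1 aa < 100
  expect_equal(find_longest_orf("ATGTAA", min_aa = 0L)$aa_length, 1L)
  long <- paste0("ATG", strrep("GCT", 120), "TAA")
  got <- find_longest_orf(long)
  expect_equal(got$aa_length, 121L)
  expect_equal(got$start, 1L)
  expect_equal(got$end, nchar(long))
  expect_equal(got$end - got$start + 1L, 3L * (got$aa_length + 1L))
  expect_null(find_longest_orf(strrep("C", 600)))      # no ATG
  # frame-shifted ORF is still found
  shifted <- paste0("GG", "ATG", strrep("AAC", 110), "TGA", "CC")
  expect_equal(find_longest_orf(shifted)$aa_length, 111L)
  # a codon containing N matches neither ATG nor a stop
  expect_null(find_longest_orf(sub("^ATG", "ATN", long)))
})

test_that("find_longest_orf agrees with the exhaustive scanner", {
  set.seed(106)
  for (rep_i in 1:200) {
    s <- random_seq(600)
    got <- find_longest_orf(s, min_aa = 0L)
    want <- brute_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$aa_length, want$aa_length)
    }
  }
})

test_that("call_utr_isoforms keeps sites spanning the first codon above threshold", {
  gene <- GRanges("c", IRanges(1000, 2000), strand = "+")
  S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
    gene_id = "g1", orf_start = 1200L, orf_end = 1800L)
  alns <- aln_set("c", "+", c(
    replicate(8, cbind(1080, 1900), simplify = FALSE),   # site -120
    replicate(12, cbind(1140, 1900), simplify = FALSE),  # site -60
    replicate(2, cbind(1100, 1900), simplify = FALSE),   # below threshold
    replicate(6, cbind(1210, 1900), simplify = FALSE)))  # misses first codon
  got <- call_utr_isoforms(gene, alns, "five_prime", threshold = 5L)
  expect_equal(got$position, c(1080L, 1140L))
  expect_equal(got$count, c(8L, 12L))

  got3 <- call_utr_isoforms(gene, aln_set("c", "+", c(
    replicate(7, cbind(1000, 1850), simplify = FALSE),   # ends before gene end
    replicate(3, cbind(1000, 1900), simplify = FALSE))), # below threshold
    "three_prime", threshold = 5L)
  expect_equal(got3$position, 1850L)
  expect_equal(got3$count, 7L)

  naked <- gene
  S4Vectors::mcols(naked)$orf_start <- NA_integer_
  expect_error(call_utr_isoforms(naked, alns, "five_prime"), "ORF")
})

test_that("call_utr_isoforms mirrors on the minus strand", {
  gene <- GRanges("c", IRanges(1000, 2000), strand = "-")
  S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
    gene_id = "g2", orf_start = 1200L, orf_end = 1800L)
  # '-' gene: 5' end is the high coordinate; first codon = [1798,1800]
  alns <- aln_set("c", "-", c(
    replicate(9, cbind(1100, 1920), simplify = FALSE),
    replicate(5, cbind(1100, 1960), simplify = FALSE)))
  got <- call_utr_isoforms(gene, alns, "five_prime", threshold = 4L)
  expect_equal(got$position, c(1960L, 1920L))  # 5' to 3' on the strand
})

test_that("find_uorfs reports every in-UTR ATG..stop span", {
  got <- find_uorfs("CCATGTTTTAACC")
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 3L)
  expect_equal(got$end, 11L)
  expect_equal(got$aa_length, 2L)
  expect_equal(nrow(find_uorfs(strrep("C", 60))), 0L)
  # ATG without an in-frame stop inside the UTR is not a uORF
  expect_equal(nrow(find_uorfs(paste0("ATG", strrep("AAC", 5)))), 0L)
})

test_that("isoform-specific uORFs are attributed to the long 5' isoform", {
  # gene on '+': ORF starts at 301; uORF lives at [121,132]; two 5' sites:
  # long isoform from 101 contains it, short isoform from 181 does not
  uorf <- paste0("ATG", "CCT", "CCG", "TAA")
  seq <- paste0(strrep("GC", 60), uorf, strrep("GC", 84), "ATGGCC")
  genome <- Biostrings::DNAStringSet(c(g = paste0(seq, strrep("GC", 50))))
  gene <- GRanges("g", IRanges(90, 400), strand = "+")
  S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
    gene_id = "snf", orf_start = 301L, orf_end = 390L)
  got <- gene_uorfs(gene, five_sites = c(101L, 181L), genome)
  expect_equal(nrow(got), 1L)
  expect_equal(got$uorf_start, 121)
  expect_equal(got$uorf_end, 132)
  expect_equal(got$present_in_isoforms[[1]], 101L)
})
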