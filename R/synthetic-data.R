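# Deterministic toy genomes and simulated full-length cDNA long reads.
#
# The generator emulates the situation the pipeline is built for: a dense
# genome (yeast-like) with mostly monoexonic genes, a minority of two-exon
# spliced genes, sense/antisense gene pairs sharing a locus, divergent
# (bidirectional-promoter) pairs, and same-strand overlapping tandem pairs
# whose reads merge into one coverage unit. Reads are full-length cDNAs:
# optional 5' SMART-like flank + transcript + poly(A) tail, emitted in either
# orientation, with indel-dominated errors.

#' Specification of a toy genome
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (nt).
#' @param n_genes Total number of genes across all chromosomes.
#' @param fraction_spliced Fraction of genes carrying one intron (two exons).
#' @param fraction_antisense_pairs Fraction of genes that are members of a
#'   sense/antisense overlapping pair (rounded to an even gene count).
#' @param fraction_bidirectional_promoters Fraction of genes in divergent
#'   pairs whose 5' ends are adjacent.
#' @param fraction_tandem_overlap Fraction of genes in same-strand pairs whose
#'   ends overlap, so that both fall into one transcriptional unit.
#' @param intergenic_min_gap Minimum gap between unrelated loci (nt).
#' @param utr5_len,utr3_len UTR lengths flanking each ORF (nt).
#' @param seed Integer seed; the same spec always yields the same genome.
#' @return An object of class `genome_spec` (a validated list).
#' @export
genome_spec <- function(n_chroms = 2L, chrom_length = 50000L, n_genes = 50L,
                        fraction_spliced = 0.2,
                        fraction_antisense_pairs = 0.16,
                        fraction_bidirectional_promoters = 0.08,
                        fraction_tandem_overlap = 0.08,
                        intergenic_min_gap = 300L,
                        utr5_len = 60L, utr3_len = 80L, seed = 1L) {
  fr <- c(fraction_spliced, fraction_antisense_pairs,
          fraction_bidirectional_promoters, fraction_tandem_overlap)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (n_genes < 1L || n_chroms < 1L) stop("need at least one gene and one chromosome")
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 fraction_spliced = fraction_spliced,
                 fraction_antisense_pairs = fraction_antisense_pairs,
                 fraction_bidirectional_promoters = fraction_bidirectional_promoters,
                 fraction_tandem_overlap = fraction_tandem_overlap,
                 intergenic_min_gap = as.integer(intergenic_min_gap),
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Remove any 10-nt window with >= 9 identical A (or T) from a character
# vector of bases, so random genomic sequence can never mimic a poly(A)/(T)
# tail under the default tail-detector settings.
cap_tail_mimics <- function(chars) {
  n <- length(chars)
  if (n < 10L) return(chars)
  repeat {
    changed <- FALSE
    for (base in c("A", "T")) {
      m <- as.integer(chars == base)
      cs <- c(0L, cumsum(m))
      sums <- cs[11:(n + 1L)] - cs[1:(n - 9L)]
      bad <- which(sums >= 9L)
      for (i in bad) {
        w <- i:(i + 9L)
        hit <- w[chars[w] == base]
        if (length(hit)) {
          # break the central base of the run so the count strictly drops
          chars[hit[ceiling(length(hit) / 2)]] <- if (base == "A") "C" else "G"
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  chars
}

#' Generate a deterministic toy genome with annotation and ground truth
#'
#' Lays out loci chromosome by chromosome with at least `intergenic_min_gap`
#' between unrelated loci. Designed pair types (antisense, bidirectional,
#' tandem-overlap) intentionally violate the gap within the pair. Spliced
#' genes have two exons and one intron; each also carries a defined minor
#' intron chain (acceptor shifted 9 nt) used by the read simulator.
#'
#' @param spec A [genome_spec()].
#' @return A list of class `toy_genome` with elements `genome`
#'   (DNAStringSet), `genes` (GRanges with mcols `gene_id`, `orf_start`,
#'   `orf_end`, `spliced`, `pair_type`), `exons` and `minor_exons`
#'   (GRangesList named by gene id), and `spec`.
#' @export
generate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    n_as <- 2L * round(spec$fraction_antisense_pairs * n / 2)
    n_bid <- 2L * round(spec$fraction_bidirectional_promoters * n / 2)
    n_tand <- 2L * round(spec$fraction_tandem_overlap * n / 2)
    n_single <- n - n_as - n_bid - n_tand
    if (n_single < 0L) stop("pair fractions exceed the gene budget")
    n_spliced <- round(spec$fraction_spliced * n)
    if (n_spliced > n_single) {
      stop("fraction_spliced too high for the number of unpaired genes")
    }

    # locus queue: each entry opens one or two genes
    loci <- c(rep("antisense", n_as %/% 2L),
              rep("bidirectional", n_bid %/% 2L),
              rep("tandem", n_tand %/% 2L),
              rep("single_spliced", n_spliced),
              rep("single", n_single - n_spliced))
    loci <- sample(loci)

    chrom_names <- sprintf("chr%02d", seq_len(spec$n_chroms))
    cursor <- setNames(rep(1L, spec$n_chroms), chrom_names)
    rows <- list()
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("g%03d", gid)
    }
    add_gene <- function(chrom, start, end, strand, spliced, pair_type) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = next_id(), chrom = chrom, start = start, end = end,
        strand = strand, spliced = spliced, pair_type = pair_type,
        stringsAsFactors = FALSE)
    }

    ci <- 0L
    for (locus in loci) {
      ci <- ci %% spec$n_chroms + 1L
      chrom <- chrom_names[ci]
      s <- cursor[chrom] + spec$intergenic_min_gap + sample(0:200, 1L)
      if (locus == "single" || locus == "single_spliced") {
        spliced <- locus == "single_spliced"
        len <- if (spliced) sample(1000:1600, 1L) else sample(600:1500, 1L)
        add_gene(chrom, s, s + len - 1L, sample(c("+", "-"), 1L), spliced, "single")
        locus_end <- s + len - 1L
      } else if (locus == "antisense") {
        len <- sample(1300:1800, 1L)
        host_strand <- sample(c("+", "-"), 1L)
        add_gene(chrom, s, s + len - 1L, host_strand, FALSE, "antisense_host")
        plen <- sample(500:700, 1L)
        ps <- s + 150L
        add_gene(chrom, ps, ps + plen - 1L,
                 if (host_strand == "+") "-" else "+", FALSE, "antisense_partner")
        locus_end <- s + len - 1L
      } else if (locus == "bidirectional") {
        lenL <- sample(600:1200, 1L)
        lenR <- sample(600:1200, 1L)
        gap0 <- sample(20:60, 1L)
        add_gene(chrom, s, s + lenL - 1L, "-", FALSE, "bidirectional")
        rs <- s + lenL + gap0
        add_gene(chrom, rs, rs + lenR - 1L, "+", FALSE, "bidirectional")
        locus_end <- rs + lenR - 1L
      } else { # tandem overlap, same strand
        st <- sample(c("+", "-"), 1L)
        len1 <- sample(700:1200, 1L)
        len2 <- sample(700:1200, 1L)
        ov <- sample(30:60, 1L)
        add_gene(chrom, s, s + len1 - 1L, st, FALSE, "tandem")
        s2 <- s + len1 - ov
        add_gene(chrom, s2, s2 + len2 - 1L, st, FALSE, "tandem")
        locus_end <- s2 + len2 - 1L
      }
      if (locus_end > spec$chrom_length - spec$intergenic_min_gap) {
        stop("gene packing infeasible; increase chrom_length or reduce n_genes")
      }
      cursor[chrom] <- locus_end
    }

    tab <- do.call(rbind, rows)
    genes <- GenomicRanges::GRanges(tab$chrom,
                                    IRanges::IRanges(tab$start, tab$end),
                                    strand = tab$strand)
    names(genes) <- tab$gene_id
    orf_start <- ifelse(tab$strand == "+", tab$start + spec$utr5_len,
                        tab$start + spec$utr3_len)
    orf_end <- ifelse(tab$strand == "+", tab$end - spec$utr3_len,
                      tab$end - spec$utr5_len)
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = tab$gene_id, orf_start = orf_start, orf_end = orf_end,
      spliced = tab$spliced, pair_type = tab$pair_type)

    # exon structures (and a designed minor chain for spliced genes)
    exons <- list()
    minor_exons <- list()
    for (i in seq_along(genes)) {
      g <- genes[i]
      if (tab$spliced[i]) {
        w1 <- sample(250:450, 1L)
        wi <- sample(120:300, 1L)
        e1 <- IRanges::IRanges(tab$start[i], tab$start[i] + w1 - 1L)
        e2 <- IRanges::IRanges(tab$start[i] + w1 + wi, tab$end[i])
        exons[[tab$gene_id[i]]] <- GenomicRanges::GRanges(
          tab$chrom[i], c(e1, e2), strand = tab$strand[i])
        # minor chain: acceptor side of the intron moved 9 nt into exon 2
        e2m <- IRanges::IRanges(tab$start[i] + w1 + wi + 9L, tab$end[i])
        minor_exons[[tab$gene_id[i]]] <- GenomicRanges::GRanges(
          tab$chrom[i], c(e1, e2m), strand = tab$strand[i])
      } else {
        exons[[tab$gene_id[i]]] <- GenomicRanges::GRanges(
          tab$chrom[i], IRanges::IRanges(tab$start[i], tab$end[i]),
          strand = tab$strand[i])
      }
    }

    # random sequence, with poly(A)/(T)-mimicking windows removed
    genome <- Biostrings::DNAStringSet(vapply(chrom_names, function(ch) {
      chars <- sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE)
      paste0(cap_tail_mimics(chars), collapse = "")
    }, character(1)))
    names(genome) <- chrom_names

    structure(list(genome = genome, genes = genes,
                   exons = GenomicRanges::GRangesList(exons),
                   minor_exons = GenomicRanges::GRangesList(minor_exons),
                   spec = spec),
              class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$genome), "chromosome(s),",
      length(x$genes), "genes (",
      sum(S4Vectors::mcols(x$genes)$spliced), "spliced )\n")
  invisible(x)
}

#' Write a toy genome as FASTA + GFF3
#'
#' @param tg A `toy_genome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @export
write_genome <- function(tg, dir) {
  stopifnot(inherits(tg, "toy_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(tg$genome, fasta)
  write_annotation(tg$genes, tg$exons, gff)
  invisible(c(fasta = fasta, gff3 = gff))
}

#' Write a gene annotation as GFF3
#'
#' Emits `gene`, `exon` and `CDS` features; the CDS interval is the ORF.
#'
#' @param genes GRanges with mcols `gene_id`, `orf_start`, `orf_end`.
#' @param exons GRangesList named by gene id.
#' @param path Output GFF3 path.
#' @export
write_annotation <- function(genes, exons, path) {
  mc <- S4Vectors::mcols(genes)
  feats <- list()
  for (i in seq_along(genes)) {
    gid <- mc$gene_id[i]
    g <- genes[i]
    S4Vectors::mcols(g) <- NULL
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(type = "gene", ID = gid, Parent = NA_character_,
                                       phase = NA_integer_)
    ex <- exons[[gid]]
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      type = "exon", ID = sprintf("%s.e%d", gid, seq_along(ex)), Parent = gid,
      phase = NA_integer_)
    cds <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                  IRanges::IRanges(mc$orf_start[i], mc$orf_end[i]),
                                  strand = GenomicRanges::strand(g))
    S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
      type = "CDS", ID = paste0(gid, ".cds"), Parent = gid, phase = 0L)
    feats[[i]] <- c(g, ex, cds)
  }
  all <- do.call(c, feats)
  S4Vectors::mcols(all)$type <- factor(S4Vectors::mcols(all)$type,
                                       levels = c("gene", "exon", "CDS"))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation written by [write_annotation()]
#'
#' @param path GFF3 file with `gene`, `exon` and `CDS` features.
#' @return A list with `genes` (GRanges, mcols `gene_id`, `orf_start`,
#'   `orf_end`, `spliced`) and `exons` (GRangesList named by gene id).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  genes <- gr[mc$type == "gene"]
  gids <- unlist(S4Vectors::mcols(genes)$ID)
  ex <- gr[mc$type == "exon"]
  cds <- gr[mc$type == "CDS"]
  ex_parent <- as.character(unlist(S4Vectors::mcols(ex)$Parent))
  cds_parent <- as.character(unlist(S4Vectors::mcols(cds)$Parent))
  exl <- GenomicRanges::GRangesList(lapply(gids, function(g) {
    x <- ex[ex_parent == g]
    S4Vectors::mcols(x) <- NULL
    GenomicRanges::sort(x, ignore.strand = TRUE)
  }))
  names(exl) <- gids
  orf_start <- orf_end <- rep(NA_integer_, length(gids))
  for (i in seq_along(gids)) {
    x <- cds[cds_parent == gids[i]]
    if (length(x)) {
      orf_start[i] <- min(GenomicRanges::start(x))
      orf_end[i] <- max(GenomicRanges::end(x))
    }
  }
  out <- genes
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gids, orf_start = orf_start, orf_end = orf_end,
    spliced = S4Vectors::elementNROWS(exl) > 1L)
  names(out) <- gids
  list(genes = out, exons = exl)
}

#' Specification of a read simulation
#'
#' @param reads_per_transcript Mean reads per transcript.
#' @param dispersion Negative-binomial dispersion of per-transcript read
#'   counts; 0 means exactly `reads_per_transcript` reads each.
#' @param error_rate Per-base error rate in `[0, 0.3]`; errors are
#'   indel-biased (deletion:insertion:substitution = 1:1:1 in events, so
#'   indels:substitutions = 2:1).
#' @param tail_length_mean,tail_length_sd Poly(A) tail length distribution
#'   (normal, truncated at 12 nt).
#' @param tail_truncation_prob Probability that a read loses its tail
#'   entirely (such reads cannot be stranded).
#' @param minor_isoform_fraction For spliced genes, probability that a read
#'   carries the designed minor intron chain instead of the major one.
#' @param flank 5'-flank sequence prepended to every sense-strand cDNA
#'   (SMART-like oligo); `""` disables it.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(reads_per_transcript = 20L, dispersion = 0,
                          error_rate = 0, tail_length_mean = 30,
                          tail_length_sd = 5, tail_truncation_prob = 0,
                          minor_isoform_fraction = 0.05,
                          flank = "AAGCAGTGGTATCAACGCAGAGTAC", seed = 1L) {
  if (error_rate < 0 || error_rate > 0.3) stop("error_rate must lie in [0, 0.3]")
  pr <- c(tail_truncation_prob, minor_isoform_fraction)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(reads_per_transcript = reads_per_transcript,
                 dispersion = dispersion, error_rate = error_rate,
                 tail_length_mean = tail_length_mean,
                 tail_length_sd = tail_length_sd,
                 tail_truncation_prob = tail_truncation_prob,
                 minor_isoform_fraction = minor_isoform_fraction,
                 flank = flank, seed = as.integer(seed)),
            class = "read_sim_spec")
}

# Apply indel-biased errors to a character vector of bases.
apply_errors <- function(chars, error_rate) {
  if (error_rate == 0) return(chars)
  n <- length(chars)
  p <- error_rate / 3
  u <- runif(n)
  del <- u < p
  sub <- u >= p & u < 2 * p
  if (any(sub)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    chars[sub] <- vapply(chars[sub], function(b) {
      pool <- strsplit(alt[[b]], "")[[1]]
      pool[sample.int(3L, 1L)]
    }, character(1))
  }
  ins <- runif(n) < p
  add <- ifelse(ins, sample(c("A", "C", "G", "T"), n, replace = TRUE), "")
  out <- paste0(ifelse(del, "", chars), add)
  strsplit(paste0(out, collapse = ""), "")[[1]]
}

#' Simulate full-length cDNA long reads with ground truth
#'
#' Every read is `flank + transcript + poly(A)` on the sense strand, emitted
#' either as-is or reverse-complemented (uniformly), with optional tail
#' truncation and indel-biased errors. The returned truth table has exactly
#' one row per FASTQ record; the perfect alignments carry each read's true
#' error-free exon block structure on the genome, so the downstream pipeline
#' can run without an external aligner.
#'
#' @param tg A `toy_genome` from [generate_genome()].
#' @param spec A [read_sim_spec()].
#' @return A list of class `sim_reads`: `reads`
#'   (QualityScaledDNAStringSet), `truth` (data.frame), `alignments`
#'   (GRangesList named by read id, the perfect alignments), `spec`.
#' @export
simulate_reads <- function(tg, spec = read_sim_spec()) {
  stopifnot(inherits(tg, "toy_genome"), inherits(spec, "read_sim_spec"))
  with_seed(spec$seed, {
    mc <- S4Vectors::mcols(tg$genes)
    # transcript body sequences, once per (gene, chain)
    chain_seq <- function(gid, exl) {
      ex <- exl[[gid]]
      chrom_i <- as.character(GenomicRanges::seqnames(ex))[1]
      body <- as.character(do.call(Biostrings::xscat,
        lapply(seq_along(ex), function(j) {
          Biostrings::subseq(tg$genome[[chrom_i]],
                             GenomicRanges::start(ex)[j],
                             GenomicRanges::end(ex)[j])
        })))
      if (as.character(GenomicRanges::strand(ex))[1] == "-") {
        body <- revcomp_chr(body)
      }
      body
    }
    major_seq <- setNames(lapply(mc$gene_id, chain_seq, exl = tg$exons),
                          mc$gene_id)
    minor_seq <- setNames(lapply(names(tg$minor_exons), chain_seq,
                                 exl = tg$minor_exons),
                          names(tg$minor_exons))
    chain_key <- function(gid, exl) {
      ex <- exl[[gid]]
      ints <- blocks_to_introns(ex)
      if (length(ints) == 0L) return("")
      intron_chain_key(as.character(GenomicRanges::seqnames(ex))[1],
                       as.character(GenomicRanges::strand(ex))[1],
                       GenomicRanges::start(ints), GenomicRanges::end(ints))
    }
    major_key <- setNames(vapply(mc$gene_id, chain_key, character(1),
                                 exl = tg$exons), mc$gene_id)
    minor_key <- setNames(vapply(names(tg$minor_exons), chain_key,
                                 character(1), exl = tg$minor_exons),
                          names(tg$minor_exons))
    seqs <- list(); quals <- list(); truth <- list(); blocks <- list()
    k <- 0L
    for (i in seq_along(tg$genes)) {
      gid <- mc$gene_id[i]
      strand_i <- as.character(GenomicRanges::strand(tg$genes[i]))
      chrom_i <- as.character(GenomicRanges::seqnames(tg$genes[i]))
      n_i <- if (spec$dispersion == 0) spec$reads_per_transcript else {
        max(1L, stats::rnbinom(1L, mu = spec$reads_per_transcript,
                               size = 1 / spec$dispersion))
      }
      for (r in seq_len(n_i)) {
        k <- k + 1L
        minor <- mc$spliced[i] && runif(1) < spec$minor_isoform_fraction
        ex <- if (minor) tg$minor_exons[[gid]] else tg$exons[[gid]]
        body <- if (minor) minor_seq[[gid]] else major_seq[[gid]]
        has_tail <- runif(1) >= spec$tail_truncation_prob
        tail_len <- if (has_tail) {
          max(12L, round(rnorm(1, spec$tail_length_mean, spec$tail_length_sd)))
        } else 0L
        sense <- paste0(spec$flank, body, strrep("A", tail_len))
        antisense <- runif(1) < 0.5
        read <- if (antisense) revcomp_chr(sense) else sense
        chars <- apply_errors(strsplit(read, "")[[1]], spec$error_rate)
        seqs[[k]] <- paste0(chars, collapse = "")
        quals[[k]] <- intToUtf8(33L + sample(15:30, length(chars), replace = TRUE))
        truth[[k]] <- data.frame(
          gene_id = gid,
          chain = if (!mc$spliced[i]) "mono" else if (minor) "minor" else "major",
          orientation = if (antisense) "antisense" else "sense",
          has_tail = has_tail, chrom = chrom_i, strand = strand_i,
          span_start = min(GenomicRanges::start(ex)),
          span_end = max(GenomicRanges::end(ex)),
          intron_chain = if (minor) minor_key[[gid]] else major_key[[gid]],
          stringsAsFactors = FALSE)
        blocks[[k]] <- ex
      }
    }
    ord <- sample.int(k)   # shuffled emission order
    ids <- sprintf("read%05d", seq_len(k))
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(unlist(seqs[ord])),
      Biostrings::PhredQuality(unlist(quals[ord])))
    names(reads) <- ids
    truth <- do.call(rbind, truth[ord])
    truth <- cbind(read_id = ids, truth)
    aln <- GenomicRanges::GRangesList(blocks[ord])
    names(aln) <- ids
    S4Vectors::mcols(aln)$mapq <- 60L
    structure(list(reads = reads, truth = truth, alignments = aln, spec = spec),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", length(x$reads), "reads from",
      length(unique(x$truth$gene_id)), "genes; error_rate =",
      x$spec$error_rate, "\n")
  invisible(x)
}

#' Write simulated reads to disk
#'
#' @param sim A `sim_reads` object.
#' @param dir Output directory.
#' @return Invisibly, paths of `reads.fastq`, `truth.tsv`, `perfect.bed`.
#' @export
write_sim_reads <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "reads.fastq")
  Biostrings::writeXStringSet(as(sim$reads, "DNAStringSet"), fq,
                              format = "fastq",
                              qualities = Biostrings::quality(sim$reads))
  tt <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- file.path(dir, "perfect.bed")
  rtracklayer::export(sim$alignments, bed, format = "bed")
  invisible(c(fastq = fq, truth = tt, bed = bed))
}
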