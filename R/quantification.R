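# Strand-aware read counting and RPKM.
#
# Counting is strand-aware by default: a read is assigned to a gene only
# when its recovered strand matches the gene's. This is what separates
# overlapping sense/antisense gene pairs that strand-unaware counting
# inevitably merges.

#' Assign aligned reads to genes
#'
#' Overlaps each alignment's exon blocks with the gene intervals and keeps,
#' per read, the single gene with the largest overlap; ties are discarded
#' as ambiguous. In stranded mode only same-strand overlaps are considered.
#'
#' @param alns `split_alignments` or GRangesList of exon blocks.
#' @param genes GRanges of gene intervals with a `gene_id` metadata column
#'   (or names).
#' @param stranded Require read strand == gene strand (default TRUE).
#' @return A data.frame `read_id`, `gene_id`, `overlap`, `strand_match`,
#'   one row per retained (read, best gene); attribute `ambiguous` counts
#'   ties discarded.
#' @export
assign_reads <- function(alns, genes, stranded = TRUE) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  gid <- S4Vectors::mcols(genes)$gene_id
  if (is.null(gid)) gid <- names(genes)
  ub <- unlist(grl, use.names = FALSE)
  ridx <- rep(seq_along(grl), S4Vectors::elementNROWS(grl))
  bh <- GenomicRanges::findOverlaps(ub, genes, ignore.strand = TRUE)
  if (length(bh) == 0L) {
    out <- data.frame(read_id = character(0), gene_id = character(0),
                      overlap = integer(0), strand_match = logical(0))
    attr(out, "ambiguous") <- 0L
    return(out)
  }
  bq <- S4Vectors::queryHits(bh)
  bs <- S4Vectors::subjectHits(bh)
  ov_w <- GenomicRanges::width(GenomicRanges::pintersect(
    ub[bq], genes[bs], ignore.strand = TRUE))
  pair <- paste0(ridx[bq], ".", bs)
  agg <- rowsum(ov_w, pair)
  first <- !duplicated(pair)
  q <- ridx[bq][first]
  s <- bs[first]
  ov <- as.integer(agg[match(paste0(q, ".", s), rownames(agg)), 1L])
  read_strand <- as.character(GenomicRanges::strand(unlist(range(grl))))
  sm <- read_strand[q] == as.character(GenomicRanges::strand(genes))[s]
  tab <- data.frame(read_id = names(grl)[q], gene_id = gid[s],
                    overlap = ov, strand_match = sm,
                    stringsAsFactors = FALSE)
  if (stranded) tab <- tab[tab$strand_match, , drop = FALSE]
  ambiguous <- 0L
  keep <- logical(nrow(tab))
  for (ii in split(seq_len(nrow(tab)), tab$read_id)) {
    best <- ii[tab$overlap[ii] == max(tab$overlap[ii])]
    if (length(best) == 1L) keep[best] <- TRUE else ambiguous <- ambiguous + 1L
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Count reads per gene
#'
#' @param assignments A data.frame from [assign_reads()] (or any with
#'   columns `read_id`, `gene_id`).
#' @param gene_ids Character vector fixing the output genes and their order
#'   (genes without reads get 0). Defaults to the genes present.
#' @return Named integer vector of counts.
#' @export
count_reads <- function(assignments, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sort(unique(assignments$gene_id))
  counts <- table(factor(assignments$gene_id, levels = gene_ids))
  setNames(as.integer(counts), gene_ids)
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = count / (length/1000) / (total/1e6)`; a zero count gives zero.
#'
#' @param counts Named numeric vector or matrix (genes x samples).
#' @param gene_lengths Named vector of transcript lengths (nt), matched by
#'   gene id.
#' @param totals Per-sample counted-read totals; defaults to column sums.
#' @return RPKM values with the shape of `counts`.
#' @export
compute_rpkm <- function(counts, gene_lengths, totals = NULL) {
  m <- as.matrix(counts)
  len <- gene_lengths[rownames(m)]
  if (is.null(rownames(m))) len <- gene_lengths
  if (any(is.na(len)) || any(len <= 0)) stop("gene lengths must be positive for all genes")
  if (is.null(totals)) totals <- colSums(m)
  if (any(totals <= 0)) stop("sample totals must be positive")
  out <- sweep(m / (len / 1000), 2L, totals / 1e6, "/")
  if (is.null(dim(counts))) setNames(out[, 1L], names(counts)) else out
}

#' Export a count matrix as TSV for downstream differential expression
#'
#' Writes genes x samples with a header row of sample ids and deterministic
#' row order. Comment lines record the downstream decision rule used for
#' differential expression calls (|log2 fold change| > 2 at p < 0.05),
#' which is applied by external tools, not here.
#'
#' @param counts Matrix or data.frame of counts (rownames = gene ids).
#' @param path Output TSV path.
#' @export
export_counts <- function(counts, path) {
  m <- as.matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gene counts for differential expression",
               "# downstream decision rule: |log2FC| > 2, p < 0.05"), con)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [export_counts()]
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Spearman correlation of log-transformed counts (QC helper)
#'
#' Rank correlation of `log10(x + 1)` between two samples, the usual
#' replicate-agreement readout for count data.
#'
#' @param x,y Count vectors of equal length.
#' @return Spearman's rho.
#' @export
qc_spearman <- function(x, y) {
  stats::cor(log10(x + 1), log10(y + 1), method = "spearman")
}
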