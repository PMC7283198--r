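# Splicing isoform filtering, major-isoform selection, UTR isoforms and
# ORF/uORF detection.
#
# Long reads span whole transcripts, so each split alignment directly
# represents a splicing isoform. Random nanopore errors rarely repeat at
# the same position in several reads, which motivates the two filters: an
# isoform must be supported by more than one read, and by at least a tenth
# of its locus coverage.

#' Filter splicing isoforms by support
#'
#' An isoform is kept iff `support >= min_reads` (default 2: more than one
#' read) and `support >= coverage_fraction * locus_coverage` (default a
#' tenth of the locus's maximum depth). The accounting identity
#' `detected = filtered + kept` holds on any input and is carried in the
#' `counts` attribute.
#'
#' @param groups A data.frame from [collapse_spliced()] (columns `chain`,
#'   `support`, optionally list-columns carried along).
#' @param locus_coverage Coverage of the genomic locus (maximum depth).
#' @param min_reads Minimum supporting reads (default 2).
#' @param coverage_fraction Fraction of locus coverage required (default 0.1).
#' @return The input rows ordered by descending support with a logical
#'   `kept` column; attribute `counts` holds `c(detected, filtered, kept)`.
#' @export
filter_isoforms <- function(groups, locus_coverage, min_reads = 2L,
                            coverage_fraction = 0.1) {
  if (nrow(groups) > 0L && locus_coverage < max(groups$support)) {
    stop("locus_coverage cannot be smaller than the largest isoform support")
  }
  kept <- groups$support >= min_reads &
    groups$support >= coverage_fraction * locus_coverage
  out <- groups
  out$kept <- kept
  out <- out[order(-out$support, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(detected = nrow(out),
                           filtered = sum(!out$kept),
                           kept = sum(out$kept))
  out
}

#' Remove short poly(A) terminal exons from an exon chain
#'
#' Poly(A) tails occasionally mis-map as short extra terminal exons. A
#' terminal exon no longer than `maxlen` whose strand-corrected sequence is
#' at least `frac` adenine is deleted and the chain re-derived; this repeats
#' until both terminal exons are clean. Interior exons are never removed,
#' and the last remaining exon is never removed.
#'
#' @param exons GRanges exon chain (sorted, one transcript).
#' @param genome DNAStringSet keyed by chromosome.
#' @param maxlen Maximum length of a removable exon (default 30 nt).
#' @param frac Minimum adenine fraction (default 0.8).
#' @return The cleaned exon GRanges.
#' @export
remove_polyA_exons <- function(exons, genome, maxlen = 30L, frac = 0.8) {
  repeat {
    n <- length(exons)
    if (n < 2L) return(exons)
    is_polyA <- function(i) {
      if (GenomicRanges::width(exons)[i] > maxlen) return(FALSE)
      s <- genome_correct(exons[i], genome)
      af <- Biostrings::letterFrequency(Biostrings::DNAString(s), "A") / nchar(s)
      af >= frac
    }
    drop <- c(if (is_polyA(1L)) 1L, if (is_polyA(n)) n)
    if (length(drop) == 0L) return(exons)
    exons <- exons[-drop]
  }
}

#' Select the major isoform of a splicing-event group
#'
#' The major isoform is the kept isoform with the highest supporting-read
#' frequency; ties are broken toward the 5'-most donor, then the 5'-most
#' acceptor (on the group's strand). All other isoforms are minors.
#'
#' @param isoforms A data.frame of kept isoforms (columns `chain`,
#'   `support`, list-column `introns`).
#' @param strand `"+"` or `"-"`.
#' @return A list with `major` (one-row data.frame) and `minors`.
#' @export
select_major <- function(isoforms, strand = "+") {
  if (nrow(isoforms) == 0L) stop("empty isoform group")
  first_donor <- vapply(isoforms$introns, function(g) {
    if (length(g) == 0L) return(NA_integer_)
    if (strand == "+") min(GenomicRanges::start(g)) else -max(GenomicRanges::end(g))
  }, double(1))
  first_acceptor <- vapply(isoforms$introns, function(g) {
    if (length(g) == 0L) return(NA_integer_)
    if (strand == "+") min(GenomicRanges::end(g)) else -max(GenomicRanges::start(g))
  }, double(1))
  o <- order(-isoforms$support, first_donor, first_acceptor)
  list(major = isoforms[o[1L], , drop = FALSE],
       minors = isoforms[o[-1L], , drop = FALSE])
}

#' Find the longest ORF in a stranded transcript sequence
#'
#' Scans the three forward frames (the sequence is already sense-stranded)
#' for ATG...stop spans and returns the longest. `aa_length` counts codons
#' from ATG to the stop, excluding the stop itself. Codons containing `N`
#' match neither ATG nor a stop.
#'
#' @param seq Character or DNAString transcript sequence.
#' @param min_aa Minimum length: the ORF is returned only when
#'   `aa_length > min_aa` (default 100, i.e. more than 100 amino acids).
#' @return A list `(start, end, aa_length)` in 1-based closed nt
#'   coordinates (`end` includes the stop codon), or `NULL`. The identity
#'   `end - start + 1 == 3 * (aa_length + 1)` holds.
#' @export
find_longest_orf <- function(seq, min_aa = 100L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    k <- (n - frame) %/% 3L
    if (k < 2L) next
    starts_nt <- frame + 1L + 3L * (seq_len(k) - 1L)
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0L || length(stp) == 0L) next
    # first stop strictly after each ATG
    nxt <- stp[findInterval(atg, stp) + 1L]
    valid <- !is.na(nxt)
    if (!any(valid)) next
    aa <- nxt[valid] - atg[valid]
    i <- which.max(aa)
    cand <- list(start = starts_nt[atg[valid][i]],
                 end = starts_nt[nxt[valid][i]] + 2L,
                 aa_length = aa[i])
    if (is.null(best) || cand$aa_length > best$aa_length) best <- cand
  }
  if (is.null(best) || best$aa_length <= min_aa) return(NULL)
  best
}

#' Call alternative 5'/3'-UTR isoforms of an annotated gene
#'
#' For the 5' side, candidate reads lie on the gene's strand, start at or
#' after the gene start, and span the first codon of the main ORF; their 5'
#' positions with read count strictly above `threshold` are alternative
#' start sites. The 3' side mirrors this (reads end before the gene end and
#' span the last codon). With `has_utr = FALSE` (annotation without UTRs)
#' the gene-boundary constraint is dropped and candidates are simply reads
#' spanning the start (resp. stop) codon; the farthest qualifying site then
#' estimates the gene boundary.
#'
#' @param gene A length-1 GRanges with mcols `gene_id`, `orf_start`,
#'   `orf_end`.
#' @param alns `split_alignments` or GRangesList (any tracks; the gene's
#'   track is selected internally).
#' @param kind `"five_prime"` or `"three_prime"`.
#' @param threshold Site-count threshold (default 4; strict "exceeds").
#' @param has_utr Does the annotation include UTRs in the gene interval?
#' @return A data.frame `gene_id`, `kind`, `position`, `count` (sites
#'   ordered 5' to 3'); attribute `gene_boundary` when `has_utr = FALSE`.
#' @export
call_utr_isoforms <- function(gene, alns, kind = c("five_prime", "three_prime"),
                              threshold = 4L, has_utr = TRUE) {
  kind <- match.arg(kind)
  mc <- S4Vectors::mcols(gene)
  if (is.null(mc$orf_start) || is.na(mc$orf_start)) {
    stop("gene lacks ORF coordinates")
  }
  strand <- as.character(GenomicRanges::strand(gene))
  chrom <- as.character(GenomicRanges::seqnames(gene))
  grl <- track_subset(alns, chrom, strand)
  if (length(grl) == 0L) {
    return(data.frame(gene_id = character(0), kind = character(0),
                      position = integer(0), count = integer(0)))
  }
  sp <- unlist(range(grl))
  rs <- GenomicRanges::start(sp)
  re <- GenomicRanges::end(sp)
  plus <- strand == "+"
  five <- if (plus) rs else re
  three <- if (plus) re else rs
  # first/last codon of the ORF in genomic coordinates
  first_codon <- if (plus) c(mc$orf_start, mc$orf_start + 2L) else c(mc$orf_end - 2L, mc$orf_end)
  last_codon <- if (plus) c(mc$orf_end - 2L, mc$orf_end) else c(mc$orf_start, mc$orf_start + 2L)
  gene_start <- if (plus) GenomicRanges::start(gene) else GenomicRanges::end(gene)
  gene_end <- if (plus) GenomicRanges::end(gene) else GenomicRanges::start(gene)
  spans <- function(codon) rs <= codon[1L] & re >= codon[2L]
  if (kind == "five_prime") {
    cand <- spans(first_codon)
    if (has_utr) {
      cand <- cand & (if (plus) five >= gene_start else five <= gene_start)
    }
    sites <- count_positions(five[cand])
  } else {
    cand <- spans(last_codon)
    if (has_utr) {
      cand <- cand & (if (plus) three <= gene_end else three >= gene_end)
    }
    sites <- count_positions(three[cand])
  }
  sites <- sites[sites > threshold]
  pos <- as.integer(names(sites))
  o <- if (plus) order(pos) else order(-pos)
  out <- data.frame(gene_id = rep(mc$gene_id, length(sites))[o],
                    kind = rep(kind, length(sites))[o],
                    position = pos[o], count = as.integer(sites)[o],
                    stringsAsFactors = FALSE)
  if (!has_utr && nrow(out) > 0L) {
    # farthest qualifying end estimates the unannotated gene boundary
    attr(out, "gene_boundary") <- if (kind == "five_prime") {
      if (plus) min(pos) else max(pos)
    } else {
      if (plus) max(pos) else min(pos)
    }
  }
  out
}

#' Find upstream ORFs in a 5'-UTR sequence
#'
#' Reports every ATG with an in-frame stop lying fully within the UTR
#' sequence (any of the three frames). The minimal uORF is ATG plus a stop
#' (`aa_length` 1, two codons including the stop).
#'
#' @param utr_seq Stranded 5'-UTR sequence (character or DNAString), i.e.
#'   the transcript sequence upstream of the main ATG.
#' @return A data.frame `start`, `end`, `aa_length` (1-based closed nt
#'   coordinates within the UTR), ordered by `start`.
#' @export
find_uorfs <- function(utr_seq) {
  seq <- toupper(as.character(utr_seq))
  n <- nchar(seq)
  rows <- list()
  for (frame in 0:2) {
    k <- (n - frame) %/% 3L
    if (k < 2L) next
    starts_nt <- frame + 1L + 3L * (seq_len(k) - 1L)
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0L || length(stp) == 0L) next
    nxt <- stp[findInterval(atg, stp) + 1L]
    valid <- !is.na(nxt)
    if (!any(valid)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts_nt[atg[valid]],
      end = starts_nt[nxt[valid]] + 2L,
      aa_length = nxt[valid] - atg[valid])
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      aa_length = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' uORFs of a gene across its alternative 5'-UTR isoforms
#'
#' For each alternative 5' start site, the genome-corrected UTR sequence
#' (site to the base before the main ATG) is scanned with [find_uorfs()];
#' uORFs are then aggregated by genomic location with the list of 5' sites
#' whose UTR contains them, so isoform-specific uORFs (present in a long
#' 5'-UTR isoform but absent from a short one) are visible.
#'
#' @param gene A length-1 GRanges with mcols `gene_id`, `orf_start`,
#'   `orf_end`.
#' @param five_sites Integer vector of alternative 5' start positions
#'   (genomic), e.g. the `position` column of [call_utr_isoforms()].
#' @param genome DNAStringSet keyed by chromosome.
#' @return A data.frame `gene_id`, `uorf_start`, `uorf_end` (genomic),
#'   `aa_length`, and list-column `present_in_isoforms` (the 5' sites whose
#'   UTR contains the uORF).
#' @export
gene_uorfs <- function(gene, five_sites, genome) {
  mc <- S4Vectors::mcols(gene)
  strand <- as.character(GenomicRanges::strand(gene))
  chrom <- as.character(GenomicRanges::seqnames(gene))
  plus <- strand == "+"
  found <- list()
  for (s in five_sites) {
    utr_iv <- if (plus) {
      if (s > mc$orf_start - 1L) next
      GenomicRanges::GRanges(chrom, IRanges::IRanges(s, mc$orf_start - 1L),
                             strand = strand)
    } else {
      if (s < mc$orf_end + 1L) next
      GenomicRanges::GRanges(chrom, IRanges::IRanges(mc$orf_end + 1L, s),
                             strand = strand)
    }
    useq <- genome_correct(utr_iv, genome)
    uo <- find_uorfs(useq)
    if (nrow(uo) == 0L) next
    # transcript/UTR coordinates -> genomic
    gstart <- if (plus) s + uo$start - 1L else s - uo$end + 1L
    gend <- if (plus) s + uo$end - 1L else s - uo$start + 1L
    for (j in seq_len(nrow(uo))) {
      key <- paste0(gstart[j], "-", gend[j])
      if (is.null(found[[key]])) {
        found[[key]] <- list(start = gstart[j], end = gend[j],
                             aa = uo$aa_length[j], sites = s)
      } else {
        found[[key]]$sites <- c(found[[key]]$sites, s)
      }
    }
  }
  if (length(found) == 0L) {
    return(data.frame(gene_id = character(0), uorf_start = integer(0),
                      uorf_end = integer(0), aa_length = integer(0),
                      present_in_isoforms = I(list())))
  }
  out <- data.frame(
    gene_id = mc$gene_id,
    uorf_start = vapply(found, `[[`, double(1), "start"),
    uorf_end = vapply(found, `[[`, double(1), "end"),
    aa_length = vapply(found, `[[`, double(1), "aa"),
    stringsAsFactors = FALSE)
  out$present_in_isoforms <- lapply(found, `[[`, "sites")
  out <- out[order(out$uorf_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
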