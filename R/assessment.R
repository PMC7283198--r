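# Assessment of a reconstructed transcriptome against a reference, at the
# isoform (intron-chain), transcript and junction levels.
#
# Sensitivity is correct calls over the expressed reference; specificity is
# correct calls over predictions. Percentages are reported to the nearest
# whole percent. Transcript-level matching is deliberately loose at the
# boundaries (UTR annotation is unreliable): each end may differ by up to
# 40% of the reference gene length, which still rejects artifact fusion
# transcripts.

#' Build an assessment report from raw counts
#'
#' @param n_correct Number of correct calls.
#' @param n_actual Size of the (expressed) reference set.
#' @param n_predicted Number of predictions.
#' @param level One of `"isoform"`, `"transcript"`, `"junction"`.
#' @return A one-row data.frame of class `assessment_report` with
#'   `sensitivity_pct = round(100 * n_correct / n_actual)` and
#'   `specificity_pct = round(100 * n_correct / n_predicted)`; a zero
#'   denominator yields 0 with the `undefined` flag set.
#' @export
assessment_report <- function(n_correct, n_actual, n_predicted,
                              level = c("transcript", "isoform", "junction")) {
  level <- match.arg(level)
  undefined <- character(0)
  sens <- if (n_actual > 0L) round(100 * n_correct / n_actual) else {
    undefined <- c(undefined, "sensitivity"); 0
  }
  spec <- if (n_predicted > 0L) round(100 * n_correct / n_predicted) else {
    undefined <- c(undefined, "specificity"); 0
  }
  out <- data.frame(level = level, n_correct = n_correct,
                    n_actual = n_actual, n_predicted = n_predicted,
                    sensitivity_pct = sens, specificity_pct = spec)
  attr(out, "undefined") <- undefined
  class(out) <- c("assessment_report", "data.frame")
  out
}

#' Expressed reference gene set
#'
#' Genes whose expression value strictly exceeds the cutoff ("more than
#' four transcripts" is the default reading).
#'
#' @param expression Named numeric vector gene -> expression value
#'   (transcript count or RPKM).
#' @param cutoff Strict cutoff (default 4).
#' @return Character vector of gene ids.
#' @export
expressed_reference <- function(expression, cutoff = 4) {
  stopifnot(all(expression >= 0))
  names(expression)[expression > cutoff]
}

#' Isoform-level metrics: exact intron-chain agreement
#'
#' A prediction is correct iff its intron chain equals the reference
#' gene's chain exactly (all donors and acceptors).
#'
#' @param predicted_chains Named character vector gene -> intron-chain key
#'   (see [intron_chain_key()]); typically from [chains_by_gene()].
#' @param reference_chains Named character vector for the reference spliced
#'   genes.
#' @return An [assessment_report()] at the isoform level.
#' @export
isoform_metrics <- function(predicted_chains, reference_chains) {
  common <- intersect(names(predicted_chains), names(reference_chains))
  n_correct <- sum(predicted_chains[common] == reference_chains[common])
  assessment_report(n_correct, length(reference_chains),
                    length(predicted_chains), "isoform")
}

#' Intron chains of predicted models, keyed by reference gene
#'
#' Maps each spliced model to the same-strand overlapping reference gene
#' (largest overlap) and returns one chain per gene (the chain of the
#' best-supported model). Models not overlapping any reference gene are
#' keyed by their own transcript id, so they still count as predictions.
#'
#' @param models `transcript_models` or GRanges with an `exons` GRangesList
#'   column.
#' @param genes Reference GRanges with `gene_id` mcols.
#' @return Named character vector gene/transcript id -> chain key.
#' @export
chains_by_gene <- function(models, genes) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  if (length(gr) == 0L) return(setNames(character(0), character(0)))
  exl <- S4Vectors::mcols(gr)$exons
  spliced <- S4Vectors::elementNROWS(exl) > 1L
  gr <- gr[spliced]
  exl <- exl[spliced]
  if (length(gr) == 0L) return(setNames(character(0), character(0)))
  keys <- vapply(seq_along(gr), function(i) {
    ints <- blocks_to_introns(exl[[i]])
    intron_chain_key(as.character(GenomicRanges::seqnames(gr))[i],
                     as.character(GenomicRanges::strand(gr))[i],
                     GenomicRanges::start(ints), GenomicRanges::end(ints))
  }, character(1))
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = FALSE)
  owner <- rep(NA_character_, length(gr))
  gid <- S4Vectors::mcols(genes)$gene_id
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[q], genes[s]))
    for (i in unique(q)) {
      sel <- which(q == i)
      owner[i] <- gid[s[sel[which.max(ov[sel])]]]
    }
  }
  owner[is.na(owner)] <- S4Vectors::mcols(gr)$transcript_id[is.na(owner)]
  sup <- S4Vectors::mcols(gr)$support
  if (is.null(sup)) sup <- rep(1L, length(gr))
  o <- order(owner, -sup)
  dedup <- !duplicated(owner[o])
  setNames(keys[o][dedup], owner[o][dedup])
}

#' Transcript-level match with boundary tolerance
#'
#' `pred` matches `ref` iff they overlap, strands agree, and each boundary
#' differs by at most `tol_frac` times the length of the tolerance base
#' (the reference by default).
#'
#' @param pred,ref GRanges of equal length (element-wise comparison).
#' @param tol_frac Boundary tolerance fraction (default 0.4).
#' @param tol_base `"ref"` (default) or `"pred"`: whose length scales the
#'   tolerance.
#' @param ignore_strand Drop the strand requirement (default FALSE).
#' @return Logical vector.
#' @export
transcript_match <- function(pred, ref, tol_frac = 0.4, tol_base = "ref",
                             ignore_strand = FALSE) {
  stopifnot(length(pred) == length(ref))
  if (length(pred) == 0L) return(logical(0))
  same_chrom <- as.character(GenomicRanges::seqnames(pred)) ==
    as.character(GenomicRanges::seqnames(ref))
  overlap <- GenomicRanges::start(pred) <= GenomicRanges::end(ref) &
    GenomicRanges::start(ref) <= GenomicRanges::end(pred)
  strand_ok <- ignore_strand |
    as.character(GenomicRanges::strand(pred)) ==
      as.character(GenomicRanges::strand(ref))
  tol <- tol_frac * if (tol_base == "ref") {
    GenomicRanges::width(ref)
  } else {
    GenomicRanges::width(pred)
  }
  ends_ok <- abs(GenomicRanges::start(pred) - GenomicRanges::start(ref)) <= tol &
    abs(GenomicRanges::end(pred) - GenomicRanges::end(ref)) <= tol
  same_chrom & overlap & strand_ok & ends_ok
}

# All (prediction, reference) index pairs passing transcript_match.
match_pairs <- function(models, ref_genes, tol_frac = 0.4,
                        ignore_strand = FALSE) {
  hits <- GenomicRanges::findOverlaps(models, ref_genes,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(pred = integer(0), ref = integer(0)))
  }
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ok <- transcript_match(models[q], ref_genes[s], tol_frac = tol_frac,
                         ignore_strand = ignore_strand)
  data.frame(pred = q[ok], ref = s[ok])
}

#' Transcript-level metrics
#'
#' A prediction is correct when it matches at least one expressed reference
#' gene under [transcript_match()]; each reference gene is creditable once,
#' so `n_correct` is the number of reference genes recovered.
#'
#' @param models `transcript_models` or GRanges of predictions.
#' @param ref_genes GRanges of expressed reference genes.
#' @param tol_frac Boundary tolerance fraction (default 0.4).
#' @param ignore_strand Drop the strand requirement (default FALSE).
#' @return An [assessment_report()] at the transcript level.
#' @export
transcript_metrics <- function(models, ref_genes, tol_frac = 0.4,
                               ignore_strand = FALSE) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  mp <- match_pairs(gr, ref_genes, tol_frac, ignore_strand)
  assessment_report(length(unique(mp$ref)), length(ref_genes), length(gr),
                    "transcript")
}

#' Junction-level metrics
#'
#' Correct junctions are the exact set intersection of predicted and
#' reference `(chrom, donor, acceptor, strand)` tuples.
#'
#' @param predicted,reference GRanges of introns (or character keys).
#' @return An [assessment_report()] at the junction level.
#' @export
junction_metrics <- function(predicted, reference) {
  as_keys <- function(x) {
    if (is.character(x)) return(unique(x))
    unique(paste0(as.character(GenomicRanges::seqnames(x)), ":",
                  GenomicRanges::start(x), "-", GenomicRanges::end(x), ":",
                  as.character(GenomicRanges::strand(x))))
  }
  p <- as_keys(predicted)
  r <- as_keys(reference)
  assessment_report(length(intersect(p, r)), length(r), length(p), "junction")
}

#' Junction set of a model collection
#'
#' @param models `transcript_models` or GRanges with an `exons` column.
#' @return GRanges of distinct introns.
#' @export
model_junctions <- function(models) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  if (length(gr) == 0L) return(GenomicRanges::GRanges())
  exl <- S4Vectors::mcols(gr)$exons
  ints <- lapply(seq_along(gr), function(i) blocks_to_introns(exl[[i]]))
  out <- do.call(c, ints)
  unique(out)
}

#' Count duplicated transcripts
#'
#' Duplicates are models beyond the first that match the same reference
#' gene under [transcript_match()] — several predictions representing one
#' gene with slight differences.
#'
#' @inheritParams transcript_metrics
#' @return Integer count of duplicates.
#' @export
count_duplicates <- function(models, ref_genes, tol_frac = 0.4) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  mp <- match_pairs(gr, ref_genes, tol_frac)
  if (nrow(mp) == 0L) return(0L)
  per_gene <- table(mp$ref)
  sum(pmax(as.integer(per_gene) - 1L, 0L))
}

#' Overlap of novel models with an external transcript catalogue
#'
#' @param novel GRanges of novel (unannotated) models.
#' @param catalogue GRanges with a `category` metadata column (e.g. SUT,
#'   CUT, XUT classes), typically imported from a user-supplied BED file.
#' @return A data.frame `category`, `n`, `n_overlapped`, `fraction`
#'   (fraction of catalogue entries with >= 1 bp same-strand overlap).
#' @export
overlap_catalogue <- function(novel, catalogue) {
  if (is.null(catalogue) || length(catalogue) == 0L) {
    message("no catalogue entries; skipping overlap computation")
    return(data.frame(category = character(0), n = integer(0),
                      n_overlapped = integer(0), fraction = numeric(0)))
  }
  cat_lab <- S4Vectors::mcols(catalogue)$category
  if (is.null(cat_lab)) cat_lab <- rep("all", length(catalogue))
  hit <- GenomicRanges::countOverlaps(catalogue, novel,
                                      ignore.strand = FALSE) > 0L
  out <- do.call(rbind, lapply(unique(cat_lab), function(cc) {
    sel <- cat_lab == cc
    data.frame(category = cc, n = sum(sel), n_overlapped = sum(hit[sel]),
               fraction = sum(hit[sel]) / sum(sel))
  }))
  rownames(out) <- NULL
  out
}
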