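# Genome-guided transcript reconstruction from per-strand coverage and
# transcript end-site profiles.
#
# The reconstruction walks each (chromosome, strand) coverage track and
# records a transcriptional unit wherever depth exceeds a pre-set threshold,
# ending it where depth falls back to or below the threshold. A unit may
# hold several overlapping genes (dense genomes, read-through); clustered
# 3' end sites inside the unit body mark where one gene ends, and the
# strongest downstream 5' site marks where the next begins. Spliced reads
# are collapsed by exact intron-chain identity and the major isoform
# defines the exon structure of a spliced gene's model.

#' Segment a coverage track into transcriptional units
#'
#' A unit is a maximal run of positions with depth strictly greater than
#' `threshold` ("exceeds" is strict, and the unit ends where coverage falls
#' below the same threshold).
#'
#' @param track A [compute_coverage()] result (or a bare integer/Rle vector).
#' @param threshold Integer depth threshold (>= 1).
#' @return A GRanges of disjoint, sorted unit intervals (strand-set when the
#'   input is a `coverage_track`).
#' @export
segment_units <- function(track, threshold) {
  stopifnot(threshold >= 1L)
  depth <- if (inherits(track, "coverage_track")) track$depth else S4Vectors::Rle(track)
  if (length(depth) == 0L) return(GenomicRanges::GRanges())
  ir <- IRanges::ranges(IRanges::slice(depth, lower = threshold + 1L))
  if (length(ir) == 0L) return(GenomicRanges::GRanges())
  if (inherits(track, "coverage_track")) {
    GenomicRanges::GRanges(track$chrom, ir, strand = track$strand)
  } else {
    GenomicRanges::GRanges("track", ir)
  }
}

#' Assign member alignments to units
#'
#' @param units GRanges of unit intervals.
#' @param alns `split_alignments` or GRangesList on the same track.
#' @return A list (one element per unit) of GRangesList members; an
#'   alignment belongs to every unit any of its blocks overlaps.
#' @export
unit_members <- function(units, alns) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  hits <- GenomicRanges::findOverlaps(units, grl, ignore.strand = FALSE)
  lapply(seq_along(units), function(i) {
    grl[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
  })
}

#' Cluster transcript end sites by gap linkage
#'
#' Transcript 3' ends disperse over a small region rather than one exact
#' base; sorted positions are joined into one cluster while consecutive
#' positions are at most `cluster_gap` nt apart. The representative is the
#' position with the highest count, ties broken 5'-most on the given strand.
#'
#' @param site_counts Named integer vector position -> count (as in
#'   [collect_end_sites()]).
#' @param cluster_gap Maximum joining gap (nt, >= 0).
#' @param strand `"+"` or `"-"` (controls the 5'-most tie break).
#' @return A data.frame with one row per cluster: `representative`,
#'   `total_count`, `start`, `end`, `n_sites`, ordered by position.
#' @export
cluster_sites <- function(site_counts, cluster_gap, strand = "+") {
  stopifnot(cluster_gap >= 0L)
  if (length(site_counts) == 0L) {
    return(data.frame(representative = integer(0), total_count = integer(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0)))
  }
  pos <- as.integer(names(site_counts))
  o <- order(pos)
  pos <- pos[o]
  cnt <- as.integer(site_counts)[o]
  grp <- cumsum(c(1L, as.integer(diff(pos) > cluster_gap)))
  out <- lapply(split(seq_along(pos), grp), function(ii) {
    p <- pos[ii]; k <- cnt[ii]
    top <- which(k == max(k))
    rep_pos <- if (strand == "+") min(p[top]) else max(p[top])
    data.frame(representative = rep_pos, total_count = sum(k),
               start = min(p), end = max(p), n_sites = length(p))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Split a multi-gene transcriptional unit at internal 3' clusters
#'
#' A 3' cluster in the unit body (at least `min_gene_len` from both unit
#' edges, with at least `min_site_count` supporting reads) ends one gene at
#' its representative position; the next gene starts at the strongest 5'
#' site downstream of the cut (falling back to the next base). Cuts are
#' applied in transcription order until no qualifying cluster remains.
#'
#' @param unit A length-1 GRanges (the unit interval, strand set).
#' @param members GRangesList of member alignments.
#' @param cluster_gap Gap used to cluster 3' sites (nt).
#' @param min_site_count Minimum reads in an internal cluster to cut.
#' @param min_gene_len Minimum distance from the unit edges (and minimum
#'   piece length, nt).
#' @return A GRanges of gene intervals (ordered, disjoint); the unit itself
#'   when no qualifying internal cluster exists.
#' @export
split_unit <- function(unit, members, cluster_gap = 20L,
                       min_site_count = 5L, min_gene_len = 50L) {
  stopifnot(length(unit) == 1L)
  strand <- as.character(GenomicRanges::strand(unit))
  us <- GenomicRanges::start(unit)
  ue <- GenomicRanges::end(unit)
  prof <- collect_end_sites(members)
  cl <- cluster_sites(prof$three_prime, cluster_gap, strand)
  internal <- cl[cl$total_count >= min_site_count &
                 cl$representative - us >= min_gene_len &
                 ue - cl$representative >= min_gene_len, , drop = FALSE]
  if (nrow(internal) == 0L) {
    out <- unit
    S4Vectors::mcols(out) <- NULL
    return(out)
  }
  five <- prof$five_prime
  five_pos <- as.integer(names(five))
  pick_five <- function(cond_pos) {
    sel <- which(cond_pos)
    if (length(sel) == 0L) return(NA_integer_)
    p <- five_pos[sel]; k <- as.integer(five)[sel]
    top <- p[k == max(k)]
    if (strand == "+") min(top) else max(top)
  }
  starts <- integer(0); ends <- integer(0)
  if (strand == "+") {
    cur <- us
    for (r in sort(internal$representative)) {
      if (r - cur + 1L < min_gene_len) next
      starts <- c(starts, cur); ends <- c(ends, r)
      nxt <- pick_five(five_pos > r)
      cur <- if (is.na(nxt) || nxt > ue) r + 1L else nxt
    }
    starts <- c(starts, cur); ends <- c(ends, ue)
  } else {
    cur <- ue
    for (r in sort(internal$representative, decreasing = TRUE)) {
      if (cur - r + 1L < min_gene_len) next
      starts <- c(starts, r); ends <- c(ends, cur)
      nxt <- pick_five(five_pos < r)
      cur <- if (is.na(nxt) || nxt < us) r - 1L else nxt
    }
    starts <- c(starts, us); ends <- c(ends, cur)
  }
  keep <- ends - starts + 1L >= 1L
  gr <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(unit)),
                               IRanges::IRanges(starts[keep], ends[keep]),
                               strand = strand)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Collapse spliced alignments by exact intron-chain identity
#'
#' Groups same-strand alignments whose donor/acceptor pairs all coincide;
#' unspliced (single-block) alignments are excluded.
#'
#' @param alns `split_alignments` or GRangesList on one strand.
#' @return A data.frame with one row per distinct chain: `chain` (key as in
#'   [intron_chain_key()]), `support`, and list-columns `introns` (GRanges)
#'   and `read_ids`.
#' @export
collapse_spliced <- function(alns) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  nb <- S4Vectors::elementNROWS(grl)
  grl <- grl[nb >= 2L]
  if (length(grl) == 0L) {
    return(data.frame(chain = character(0), support = integer(0),
                      introns = I(list()), read_ids = I(list())))
  }
  sp <- unlist(range(grl))
  ints_l <- IRanges::psetdiff(sp, grl)
  keys <- paste0(
    as.character(GenomicRanges::seqnames(sp)), ":",
    as.character(GenomicRanges::strand(sp)), ":",
    vapply(seq_along(ints_l), function(i) {
      paste0(GenomicRanges::start(ints_l[[i]]), "-",
             GenomicRanges::end(ints_l[[i]]), collapse = ";")
    }, character(1)))
  ids <- names(grl)
  if (is.null(ids)) ids <- as.character(seq_along(grl))
  groups <- split(seq_along(grl), keys)
  out <- data.frame(chain = names(groups),
                    support = vapply(groups, length, integer(1)),
                    stringsAsFactors = FALSE)
  out$introns <- lapply(groups, function(ii) ints_l[[ii[1L]]])
  out$read_ids <- lapply(groups, function(ii) ids[ii])
  out <- out[order(-out$support, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exon chain of a gene interval given an intron GRanges (introns must lie
# inside the interval; those outside are dropped).
chain_to_exons <- function(interval, introns) {
  s <- GenomicRanges::start(interval)
  e <- GenomicRanges::end(interval)
  keep <- GenomicRanges::start(introns) > s & GenomicRanges::end(introns) < e
  introns <- introns[keep]
  if (length(introns) == 0L) {
    gr <- interval
    S4Vectors::mcols(gr) <- NULL
    return(gr)
  }
  o <- order(GenomicRanges::start(introns))
  is_ <- GenomicRanges::start(introns)[o]
  ie_ <- GenomicRanges::end(introns)[o]
  GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(interval)),
                         IRanges::IRanges(c(s, ie_ + 1L), c(is_ - 1L, e)),
                         strand = GenomicRanges::strand(interval))
}

#' Build transcript models from gene intervals and spliced groups
#'
#' Coverage segmentation leaves a spliced gene as several per-exon
#' intervals (introns carry no coverage), so gene intervals connected by a
#' spliced alignment are first merged into one locus. A locus whose kept
#' spliced isoforms (see [filter_isoforms()]) include a major chain becomes
#' one model with that chain's exons; every other interval becomes a
#' single-exon model spanning itself. Short terminal exons made of poly(A)
#' sequence are removed when the genome is supplied. Minor kept isoforms
#' are reported as alternatives.
#'
#' @param gene_intervals GRanges of gene intervals on one track.
#' @param alns `split_alignments` or GRangesList on the same track.
#' @param genome Optional DNAStringSet for the poly(A)-exon check.
#' @param config A [default_config()]-style list of thresholds.
#' @return A list of class `transcript_models`: `models` (GRanges with
#'   mcols `transcript_id`, `support`, `class_label`, and an `exons`
#'   GRangesList column) and `alternatives` (data.frame of kept minor
#'   chains with `gene_interval`, `chain`, `support`).
#' @export
build_models <- function(gene_intervals, alns, genome = NULL,
                         config = default_config()) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  models <- list()
  alts <- list()
  members_by_gene <- unit_members(gene_intervals, grl)

  # union-find over gene intervals: merge intervals linked by a spliced read
  parent <- seq_along(gene_intervals)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  spliced_reads <- grl[S4Vectors::elementNROWS(grl) >= 2L]
  if (length(spliced_reads) && length(gene_intervals)) {
    hits <- GenomicRanges::findOverlaps(gene_intervals, spliced_reads,
                                        ignore.strand = FALSE)
    for (jj in split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))) {
      roots <- unique(vapply(jj, find, integer(1)))
      if (length(roots) > 1L) parent[roots[-1L]] <- roots[1L]
    }
  }
  comp <- vapply(seq_along(gene_intervals), find, integer(1))

  add_model <- function(exons, support) {
    span <- range(exons)
    strand <- as.character(GenomicRanges::strand(span))
    tid <- sprintf("%s:%d-%d:%s",
                   as.character(GenomicRanges::seqnames(span)),
                   GenomicRanges::start(span), GenomicRanges::end(span),
                   strand)
    S4Vectors::mcols(span) <- S4Vectors::DataFrame(
      transcript_id = tid, support = support, class_label = "UNSET",
      exons = GenomicRanges::GRangesList(exons))
    models[[length(models) + 1L]] <<- span
  }

  for (idx in split(seq_along(gene_intervals), comp)) {
    ivs <- gene_intervals[idx]
    members <- members_by_gene[[idx[1L]]]
    if (length(idx) > 1L) {
      nm <- unique(unlist(lapply(idx, function(i) names(members_by_gene[[i]]))))
      members <- grl[nm]
    }
    strand <- as.character(GenomicRanges::strand(ivs))[1L]
    exons <- NULL
    if (length(members) > 0L) {
      groups <- collapse_spliced(members)
      if (nrow(groups) > 0L) {
        cov <- compute_coverage(members,
                                as.character(GenomicRanges::seqnames(ivs))[1L],
                                strand)
        locus_cov <- if (length(cov$depth)) max(cov$depth) else 0L
        iso <- filter_isoforms(groups, locus_cov,
                               min_reads = config$min_isoform_reads,
                               coverage_fraction = config$isoform_coverage_fraction)
        kept <- iso[iso$kept, , drop = FALSE]
        if (nrow(kept) > 0L) {
          sel <- select_major(kept, strand = strand)
          locus_span <- range(GenomicRanges::reduce(ivs, ignore.strand = FALSE))
          exons <- chain_to_exons(locus_span, sel$major$introns[[1L]])
          if (!is.null(genome)) {
            exons <- remove_polyA_exons(exons, genome,
                                        maxlen = config$polyA_exon_maxlen,
                                        frac = config$polyA_exon_frac)
          }
          if (nrow(sel$minors) > 0L) {
            alts[[length(alts) + 1L]] <- data.frame(
              gene_interval = as.character(locus_span),
              chain = sel$minors$chain,
              support = sel$minors$support,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (is.null(exons)) {
      # no dominant spliced chain: each interval stands as its own gene
      for (i in idx) {
        iv <- gene_intervals[i]
        S4Vectors::mcols(iv) <- NULL
        add_model(iv, length(members_by_gene[[i]]))
      }
    } else {
      add_model(exons, length(members))
    }
  }
  models <- if (length(models)) do.call(c, models) else GenomicRanges::GRanges()
  if (length(models) > 1L) {
    models <- GenomicRanges::sort(models, ignore.strand = TRUE)
  }
  alternatives <- if (length(alts)) do.call(rbind, alts) else {
    data.frame(gene_interval = character(0), chain = character(0),
               support = integer(0))
  }
  structure(list(models = models, alternatives = alternatives),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", length(x$models), "models,",
      nrow(x$alternatives), "alternative isoforms\n")
  invisible(x)
}

#' Reconstruct transcript models for a whole genome
#'
#' Runs segmentation, unit splitting and model building over every
#' (chromosome, strand) track and concatenates the results.
#'
#' @param alns A `split_alignments` (all tracks together).
#' @param genome Optional DNAStringSet (enables the poly(A)-exon check).
#' @param config A [default_config()]-style list.
#' @return A `transcript_models` object.
#' @export
reconstruct_transcripts <- function(alns, genome = NULL,
                                    config = default_config()) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  sp <- unlist(range(grl))
  tracks <- unique(data.frame(chrom = as.character(GenomicRanges::seqnames(sp)),
                              strand = as.character(GenomicRanges::strand(sp)),
                              stringsAsFactors = FALSE))
  tracks <- tracks[order(tracks$chrom, tracks$strand), , drop = FALSE]
  all_models <- list()
  all_alts <- list()
  for (t in seq_len(nrow(tracks))) {
    tr <- track_subset(grl, tracks$chrom[t], tracks$strand[t])
    cov <- compute_coverage(tr, tracks$chrom[t], tracks$strand[t])
    units <- segment_units(cov, config$coverage_threshold)
    if (length(units) == 0L) next
    members <- unit_members(units, tr)
    genes <- list()
    for (u in seq_along(units)) {
      genes[[u]] <- split_unit(units[u], members[[u]],
                               cluster_gap = config$cluster_gap,
                               min_site_count = config$min_site_count,
                               min_gene_len = config$min_gene_len)
    }
    genes <- do.call(c, genes)
    bm <- build_models(genes, tr, genome = genome, config = config)
    all_models[[length(all_models) + 1L]] <- bm$models
    all_alts[[length(all_alts) + 1L]] <- bm$alternatives
  }
  # per-track GRanges carry single-chromosome seqinfo; merging them is fine
  models <- if (length(all_models)) {
    suppressWarnings(do.call(c, all_models))
  } else GenomicRanges::GRanges()
  alternatives <- if (length(all_alts)) do.call(rbind, all_alts) else {
    data.frame(gene_interval = character(0), chain = character(0),
               support = integer(0))
  }
  structure(list(models = models, alternatives = alternatives),
            class = "transcript_models")
}

#' Classify transcript models against a reference annotation
#'
#' A model overlapping an annotated ORF on the same strand (totally or
#' partly) is `ORF_OVERLAP`; otherwise an opposite-strand overlap with an
#' annotated gene makes it `ANTISENSE`; everything else is `INTERGENIC`,
#' sub-labelled from the orientation of the flanking genes: `convergent`
#' when both neighbours transcribe toward the model, `divergent` when both
#' transcribe away, otherwise `upstream`/`downstream` of the nearest gene
#' (suffixed `_convergent`/`_divergent`/`_tandem` by the relative
#' orientation of that neighbour).
#'
#' @param models A `transcript_models` or GRanges of models.
#' @param annotation Annotation list as from [read_annotation()] (GRanges
#'   `genes` with `orf_start`/`orf_end` mcols).
#' @return The models GRanges with `class_label` and `sub_label` filled in.
#' @export
classify_models <- function(models, annotation) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  genes <- annotation$genes
  mc <- S4Vectors::mcols(genes)
  orfs <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                 IRanges::IRanges(mc$orf_start, mc$orf_end),
                                 strand = GenomicRanges::strand(genes))
  if (length(gr) == 0L) return(gr)
  if (!all(as.character(GenomicRanges::seqnames(gr)) %in%
           as.character(GenomicRanges::seqnames(genes)))) {
    warning("models on chromosomes absent from the annotation; labelled INTERGENIC")
  }
  lab <- rep("INTERGENIC", length(gr))
  sub <- rep(NA_character_, length(gr))
  same_orf <- GenomicRanges::countOverlaps(gr, orfs, ignore.strand = FALSE) > 0L
  lab[same_orf] <- "ORF_OVERLAP"
  flipped <- gr
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(gr)) == "+", "-", "+")
  anti <- !same_orf &
    GenomicRanges::countOverlaps(flipped, genes, ignore.strand = FALSE) > 0L
  lab[anti] <- "ANTISENSE"
  for (i in which(lab == "INTERGENIC")) {
    sub[i] <- intergenic_sublabel(gr[i], genes)
  }
  S4Vectors::mcols(gr)$class_label <- lab
  S4Vectors::mcols(gr)$sub_label <- sub
  gr
}

# Orientation sub-label of an intergenic model from its flanking genes.
intergenic_sublabel <- function(model, genes) {
  chrom <- as.character(GenomicRanges::seqnames(model))
  g <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
  if (length(g) == 0L) return("isolated")
  left <- g[GenomicRanges::end(g) < GenomicRanges::start(model)]
  right <- g[GenomicRanges::start(g) > GenomicRanges::end(model)]
  l <- if (length(left)) left[which.max(GenomicRanges::end(left))] else NULL
  r <- if (length(right)) right[which.min(GenomicRanges::start(right))] else NULL
  if (!is.null(l) && !is.null(r)) {
    toward_l <- as.character(GenomicRanges::strand(l)) == "+"
    toward_r <- as.character(GenomicRanges::strand(r)) == "-"
    if (toward_l && toward_r) return("convergent")
    if (!toward_l && !toward_r) return("divergent")
  }
  near <- if (is.null(l)) r else if (is.null(r)) l else {
    dl <- GenomicRanges::start(model) - GenomicRanges::end(l)
    dr <- GenomicRanges::start(r) - GenomicRanges::end(model)
    if (dl <= dr) l else r
  }
  if (is.null(near)) return("isolated")
  ns <- as.character(GenomicRanges::strand(near))
  # model upstream of its neighbour = on the neighbour's 5' side
  model_left <- GenomicRanges::end(model) < GenomicRanges::start(near)
  pos <- if ((model_left && ns == "+") || (!model_left && ns == "-")) {
    "upstream"
  } else "downstream"
  ms <- as.character(GenomicRanges::strand(model))
  ori <- if (ms == ns) "tandem" else {
    facing <- (model_left && ms == "+" && ns == "-") ||
      (!model_left && ms == "-" && ns == "+")
    if (facing) "convergent" else "divergent"
  }
  paste(pos, ori, sep = "_")
}
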