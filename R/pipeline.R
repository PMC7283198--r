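# Pipeline configuration and end-to-end orchestration.

#' Default pipeline configuration
#'
#' All thresholds of the pipeline in one flat list. Paths (`reads`,
#' `genome`, `annotation`, `alignments`, `out_dir`) default to `NULL` and
#' must be set (or passed to [run_pipeline()]) as needed.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    # stranding
    search_window = 100L, min_tail_length = 10L, max_mismatch_fraction = 0.15,
    smart_oligo = NULL,
    # alignment
    aligner_cmd = "minimap2 -ax splice --secondary=no {genome} {fastq}",
    min_mapq = 0L,
    # reconstruction
    coverage_threshold = 4L, cluster_gap = 20L, min_site_count = 5L,
    min_gene_len = 50L,
    # isoform profiling
    min_isoform_reads = 2L, isoform_coverage_fraction = 0.1,
    polyA_exon_maxlen = 30L, polyA_exon_frac = 0.8, min_orf_aa = 100L,
    utr_site_threshold = 4L,
    # quantification / assessment
    stranded = TRUE, tol_frac = 0.4, expression_cutoff = 4L,
    # io
    reads = NULL, genome = NULL, annotation = NULL, alignments = NULL,
    out_dir = NULL, seed = 1L
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg
}

#' Save a pipeline configuration as YAML
#'
#' @param config A `pipeline_config` list.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' @param config A `pipeline_config` list.
#' @return An md5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Export transcript models as GTF
#'
#' Writes `transcript` and `exon` features (1-based closed, as GTF
#' requires) with `gene_id`/`transcript_id` attributes.
#'
#' @param models `transcript_models` or GRanges with an `exons` column.
#' @param path Output GTF path.
#' @export
write_models_gtf <- function(models, path) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  lines <- character(0)
  if (length(gr)) {
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    for (i in o) {
      tid <- S4Vectors::mcols(gr)$transcript_id[i]
      cls <- S4Vectors::mcols(gr)$class_label[i]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s', tid, tid,
                       if (!is.null(cls) && !is.na(cls) && cls != "UNSET") {
                         sprintf(' class "%s";', cls)
                       } else "")
      row <- function(type, s, e) {
        paste(as.character(GenomicRanges::seqnames(gr))[i], "nanotx", type,
              s, e, ".", as.character(GenomicRanges::strand(gr))[i], ".",
              attrs, sep = "\t")
      }
      lines <- c(lines, row("transcript", GenomicRanges::start(gr)[i],
                            GenomicRanges::end(gr)[i]))
      ex <- S4Vectors::mcols(gr)$exons[[i]]
      for (j in order(GenomicRanges::start(ex))) {
        lines <- c(lines, row("exon", GenomicRanges::start(ex)[j],
                              GenomicRanges::end(ex)[j]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export transcript models as BED12
#'
#' @param models `transcript_models` or GRanges with an `exons` column.
#' @param path Output BED path.
#' @export
write_models_bed <- function(models, path) {
  gr <- if (inherits(models, "transcript_models")) models$models else models
  if (length(gr) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  exl <- S4Vectors::mcols(gr)$exons
  names(exl) <- S4Vectors::mcols(gr)$transcript_id
  rtracklayer::export(exl, path, format = "bed")
  invisible(path)
}

#' Run the full pipeline
#'
#' Stage order: strand the reads, obtain split alignments (supplied
#' directly or via the external aligner), reconstruct transcript models per
#' (chromosome, strand) track, profile isoforms/UTRs/uORFs and quantify
#' against the annotation when one is given, and assess the reconstruction
#' against the expressed reference. All outputs land in `out_dir` and are
#' byte-identical across reruns with the same inputs and configuration.
#'
#' @param config A `pipeline_config` list ([default_config()] /
#'   [load_config()]), with `reads`, `genome`, `out_dir` set; `annotation`
#'   and `alignments` optional. When `alignments` is `NULL` the external
#'   aligner configured in `aligner_cmd` is run on the stranded FASTQ.
#' @return A list of class `pipeline_result` with the in-memory results and
#'   an `outputs` vector of file paths.
#' @export
run_pipeline <- function(config) {
  for (key in c("reads", "genome", "out_dir")) {
    if (is.null(config[[key]])) stop("config is missing required path: ", key)
  }
  for (key in c("reads", "genome", "annotation", "alignments")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured ", key, " file does not exist: ", p)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  log_lines <- c(paste("config_hash:", config_hash(config)))
  say <- function(...) log_lines <<- c(log_lines, paste(...))

  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  # 1. stranding
  tp <- tail_params(config$search_window, config$min_tail_length,
                    config$max_mismatch_fraction, config$smart_oligo)
  str_res <- strand_reads(config$reads, tp)
  write_fastq(str_res$reads, outp("stranded.fastq"))
  write_strand_report(str_res, outp("strand_report.tsv"))
  say("stranding:", nrow(str_res$calls), "reads in,",
      length(str_res$reads), "stranded")

  # 2. alignments
  aln_path <- config$alignments
  if (is.null(aln_path)) {
    say("aligning with:", config$aligner_cmd)
    aln_path <- align_external(outp("stranded.fastq"), config$genome,
                               out = outp("aligned.sam"),
                               cmd_template = config$aligner_cmd)
  }
  alns <- load_alignments(aln_path, min_mapq = config$min_mapq)
  keep <- S4Vectors::mcols(alns$blocks)$read_id %in% names(str_res$reads)
  alns$blocks <- alns$blocks[keep]
  say("alignments:", length(alns$blocks), "primary from stranded reads (",
      alns$n_skipped, "skipped )")

  # 3. reconstruction
  models <- reconstruct_transcripts(alns, genome, config)
  say("reconstruction:", length(models$models), "models,",
      nrow(models$alternatives), "alternative isoforms")

  annotation <- NULL
  utr5 <- utr3 <- uorfs <- NULL
  counts <- rpkm <- NULL
  assessment <- NULL
  if (!is.null(config$annotation)) {
    annotation <- read_annotation(config$annotation)
    models$models <- classify_models(models, annotation)

    # 4. UTR isoforms and uORFs per annotated gene
    utr5l <- list(); utr3l <- list(); uol <- list()
    for (i in seq_along(annotation$genes)) {
      g <- annotation$genes[i]
      u5 <- call_utr_isoforms(g, alns, "five_prime",
                              threshold = config$utr_site_threshold)
      u3 <- call_utr_isoforms(g, alns, "three_prime",
                              threshold = config$utr_site_threshold)
      if (nrow(u5)) utr5l[[length(utr5l) + 1L]] <- u5
      if (nrow(u3)) utr3l[[length(utr3l) + 1L]] <- u3
      sites <- u5$position
      if (length(sites)) {
        uo <- gene_uorfs(g, sites, genome)
        if (nrow(uo)) uol[[length(uol) + 1L]] <- uo
      }
    }
    bindo <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
    utr5 <- bindo(utr5l, data.frame(gene_id = character(0), kind = character(0),
                                    position = integer(0), count = integer(0)))
    utr3 <- bindo(utr3l, data.frame(gene_id = character(0), kind = character(0),
                                    position = integer(0), count = integer(0)))
    uorfs <- if (length(uol)) do.call(rbind, uol) else {
      data.frame(gene_id = character(0), uorf_start = integer(0),
                 uorf_end = integer(0), aa_length = integer(0))
    }
    say("isoform profiling:", nrow(utr5), "alt 5' sites,", nrow(utr3),
        "alt 3' sites,", nrow(uorfs), "uORFs")

    # 5. quantification
    asg <- assign_reads(alns, annotation$genes, stranded = config$stranded)
    gids <- S4Vectors::mcols(annotation$genes)$gene_id
    counts <- count_reads(asg, gids)
    lens <- setNames(vapply(gids, function(g) {
      sum(GenomicRanges::width(annotation$exons[[g]]))
    }, integer(1)), gids)
    rpkm <- compute_rpkm(counts, lens, totals = max(1L, sum(counts)))
    say("quantification:", sum(counts), "reads counted over",
        length(gids), "genes")

    # 6. assessment against the expressed reference
    expressed <- expressed_reference(counts, config$expression_cutoff)
    ref <- annotation$genes[gids %in% expressed]
    ref_spliced <- ref[S4Vectors::mcols(ref)$spliced]
    ref_chains <- setNames(vapply(S4Vectors::mcols(ref_spliced)$gene_id,
      function(g) {
        ints <- blocks_to_introns(annotation$exons[[g]])
        intron_chain_key(
          as.character(GenomicRanges::seqnames(annotation$exons[[g]]))[1],
          as.character(GenomicRanges::strand(annotation$exons[[g]]))[1],
          GenomicRanges::start(ints), GenomicRanges::end(ints))
      }, character(1)), S4Vectors::mcols(ref_spliced)$gene_id)
    ref_junc <- do.call(c, c(list(GenomicRanges::GRanges()),
      lapply(S4Vectors::mcols(ref_spliced)$gene_id, function(g) {
        blocks_to_introns(annotation$exons[[g]])
      })))
    assessment <- rbind(
      transcript_metrics(models, ref, tol_frac = config$tol_frac),
      isoform_metrics(chains_by_gene(models, ref_spliced), ref_chains),
      junction_metrics(model_junctions(models), ref_junc))
    say("assessment:",
        paste(assessment$level,
              paste0(assessment$sensitivity_pct, "/",
                     assessment$specificity_pct),
              collapse = "; "))
  }

  # outputs
  write_models_gtf(models, outp("models.gtf"))
  write_models_bed(models, outp("models.bed"))
  write.table(models$alternatives, outp("alternatives.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    write.table(utr5, outp("utr5_isoforms.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(utr3, outp("utr3_isoforms.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    uo_flat <- uorfs
    if (!is.null(uo_flat$present_in_isoforms)) {
      uo_flat$present_in_isoforms <- vapply(uo_flat$present_in_isoforms,
                                            paste, character(1), collapse = ",")
    }
    write.table(uo_flat, outp("uorfs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    export_counts(cbind(sample1 = counts), outp("counts.tsv"))
    write.table(data.frame(gene_id = names(rpkm), rpkm = unname(rpkm)),
                outp("rpkm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(assessment), outp("assessment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  save_config(config, outp("config_used.yaml"))
  writeLines(log_lines, outp("pipeline.log"))

  structure(list(stranding = str_res, alignments = alns, models = models,
                 utr5 = utr5, utr3 = utr3, uorfs = uorfs, counts = counts,
                 rpkm = rpkm, assessment = assessment,
                 outputs = list.files(config$out_dir, full.names = TRUE),
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$models$models), "models")
  if (!is.null(x$assessment)) {
    cat("; assessment",
        paste(x$assessment$level,
              paste0(x$assessment$sensitivity_pct, "/",
                     x$assessment$specificity_pct),
              collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
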