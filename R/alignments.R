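# Split-alignment ingestion, genome correction, per-strand coverage and
# transcript end-site profiles.
#
# A split alignment is one read's genomic placement as an ordered set of
# exon blocks on one strand; it is the unit of every downstream
# computation. Internally blocks live in GRangesList objects (1-based
# closed coordinates, the GenomicRanges idiom); BED's 0-based half-open
# convention exists only on disk and is handled by rtracklayer.

#' Load split alignments from SAM/BAM or BED12
#'
#' SAM input is converted to BAM on the fly. Only primary alignments are
#' kept; secondary/supplementary records are skipped and counted. Each
#' alignment becomes one element of a GRangesList of exon blocks (CIGAR `N`
#' gaps or BED12 blocks define the introns).
#'
#' @param path A `.sam`, `.bam` or `.bed` (BED12) file.
#' @param min_mapq Minimum mapping quality (default 0: no filter; BED
#'   records carry no mapq and are never filtered).
#' @return A list of class `split_alignments`: `blocks` (GRangesList named
#'   by read id, with mcols `read_id` and `mapq`) and `n_skipped`.
#' @export
load_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    grl <- rtracklayer::blocks(gr)
    # block arithmetic must stay inside the record span
    sp <- unlist(range(grl))
    bad <- which(GenomicRanges::start(sp) < GenomicRanges::start(gr) |
                 GenomicRanges::end(sp) > GenomicRanges::end(gr))
    if (length(bad)) {
      stop("inconsistent BED12 blocks at record ", bad[1L],
           " (", S4Vectors::mcols(gr)$name[bad[1L]], ")")
    }
    ids <- make.unique(S4Vectors::mcols(gr)$name, sep = "/")
    names(grl) <- ids
    S4Vectors::mcols(grl) <- S4Vectors::DataFrame(read_id = ids, mapq = NA_integer_)
    return(structure(list(blocks = grl, n_skipped = 0L),
                     class = "split_alignments"))
  }
  bam <- path
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param_all <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param_all)
  fl <- S4Vectors::mcols(ga)$flag
  secondary <- bitwAnd(fl, 256L) > 0L | bitwAnd(fl, 2048L) > 0L
  low_mapq <- S4Vectors::mcols(ga)$mapq < min_mapq
  low_mapq[is.na(low_mapq)] <- FALSE
  n_skipped <- sum(secondary | low_mapq)
  ga <- ga[!secondary & !low_mapq]
  grl <- GenomicAlignments::grglist(ga)
  ids <- make.unique(S4Vectors::mcols(ga)$qname, sep = "/")
  names(grl) <- ids
  S4Vectors::mcols(grl) <- S4Vectors::DataFrame(
    read_id = ids, mapq = S4Vectors::mcols(ga)$mapq)
  structure(list(blocks = grl, n_skipped = n_skipped),
            class = "split_alignments")
}

#' @export
print.split_alignments <- function(x, ...) {
  cat("split_alignments:", length(x$blocks), "primary alignments (",
      x$n_skipped, "records skipped )\n")
  invisible(x)
}

#' Run an external spliced aligner as a subprocess
#'
#' The command template must contain the placeholders `{fastq}`, `{genome}`
#' and may contain `{out}`; when `{out}` is absent, stdout is captured into
#' the output file. The default template calls minimap2 in spliced mode with
#' secondary alignments disabled.
#'
#' @param fastq Stranded FASTQ path.
#' @param genome Genome FASTA path.
#' @param out Output SAM path (default: tempfile).
#' @param cmd_template Command template string.
#' @return The output SAM path.
#' @export
align_external <- function(fastq, genome, out = tempfile(fileext = ".sam"),
                           cmd_template = "minimap2 -ax splice --secondary=no {genome} {fastq}") {
  exe <- strsplit(trimws(cmd_template), "\\s+")[[1]][1]
  if (Sys.which(exe) == "") {
    stop("aligner executable not found on PATH: ", exe,
         " (supply alignments directly or fix the aligner_cmd config)")
  }
  cmd <- cmd_template
  for (key in c("fastq", "genome", "out")) {
    cmd <- gsub(paste0("{", key, "}"),
                shQuote(get(key)), cmd, fixed = TRUE)
  }
  capture <- !grepl("{out}", cmd_template, fixed = TRUE)
  errfile <- tempfile()
  on.exit(unlink(errfile))
  st <- system2("sh", c("-c", shQuote(cmd)),
                stdout = if (capture) out else FALSE, stderr = errfile)
  if (st != 0L) {
    msg <- if (file.exists(errfile)) {
      paste(utils::tail(readLines(errfile, warn = FALSE), 5L), collapse = "\n")
    } else ""
    stop("aligner failed (exit ", st, "): ", msg)
  }
  out
}

#' Replace a read's sequence by the genomic sequence under its alignment
#'
#' Concatenates the genome over the alignment's exon blocks and
#' reverse-complements when the alignment strand is `-`. Because the result
#' is taken from the genome, it is error-free regardless of the read's own
#' error rate; it is used for ORF/uORF calling and poly(A)-exon checks.
#'
#' @param blocks A GRanges of exon blocks (one alignment) or a GRangesList.
#' @param genome A DNAStringSet keyed by chromosome name.
#' @return A character string (or vector, for a GRangesList).
#' @export
genome_correct <- function(blocks, genome) {
  if (methods::is(blocks, "GRangesList")) {
    return(vapply(seq_along(blocks), function(i) {
      genome_correct(blocks[[i]], genome)
    }, character(1)))
  }
  chrom <- as.character(GenomicRanges::seqnames(blocks))[1]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (any(GenomicRanges::end(blocks) > length(genome[[chrom]])) ||
      any(GenomicRanges::start(blocks) < 1L)) {
    stop("alignment block exceeds chromosome bounds on ", chrom)
  }
  o <- order(GenomicRanges::start(blocks))
  pieces <- lapply(o, function(j) {
    Biostrings::subseq(genome[[chrom]],
                       GenomicRanges::start(blocks)[j],
                       GenomicRanges::end(blocks)[j])
  })
  s <- do.call(Biostrings::xscat, pieces)
  if (as.character(GenomicRanges::strand(blocks))[1] == "-") {
    s <- Biostrings::reverseComplement(s)
  }
  as.character(s)
}

# Subset a split_alignments object (or bare GRangesList) to one
# chromosome/strand track.
track_subset <- function(alns, chrom, strand) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  if (length(grl) == 0L) return(grl)
  first <- unlist(range(grl))
  sel <- as.character(GenomicRanges::seqnames(first)) == chrom &
    as.character(GenomicRanges::strand(first)) == strand
  grl[sel]
}

#' Per-base read coverage of one (chromosome, strand) track
#'
#' Depth at a position is the number of alignments with an exon block
#' covering it; intronic gaps contribute nothing. Strands are processed
#' separately throughout the pipeline so antisense transcripts never
#' interfere with their sense counterparts.
#'
#' @param alns A `split_alignments` or GRangesList of exon blocks.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param chrom_length Optional track length (pads the tail with zeros).
#' @return A list of class `coverage_track`: `chrom`, `strand`, `depth`
#'   (integer Rle).
#' @export
compute_coverage <- function(alns, chrom, strand, chrom_length = NULL) {
  grl <- track_subset(alns, chrom, strand)
  u <- unlist(grl, use.names = FALSE)
  if (length(u) == 0L) {
    len <- if (is.null(chrom_length)) 0L else chrom_length
    depth <- S4Vectors::Rle(0L, len)
  } else {
    depth <- GenomicRanges::coverage(u)[[chrom]]
    if (!is.null(chrom_length) && length(depth) < chrom_length) {
      depth <- c(depth, S4Vectors::Rle(0L, chrom_length - length(depth)))
    }
  }
  structure(list(chrom = chrom, strand = strand, depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", paste0(x$chrom, ":", x$strand), "length",
      length(x$depth), "max depth", if (length(x$depth)) max(x$depth) else 0, "\n")
  invisible(x)
}

#' Transcript end-site profile of a set of alignments
#'
#' For a `+` alignment the 5' site is the first block's start and the 3'
#' site the last block's end (the last covered base); mirrored for `-`.
#' Counts sum to the number of alignments on each side.
#'
#' @param alns A `split_alignments` or GRangesList sharing one
#'   chromosome and strand.
#' @return A list of class `end_profile` with `five_prime` and
#'   `three_prime`, each a named integer vector position -> read count.
#' @export
collect_end_sites <- function(alns) {
  grl <- if (inherits(alns, "split_alignments")) alns$blocks else alns
  check_single_track(grl)
  if (length(grl) == 0L) {
    empty <- setNames(integer(0), character(0))
    return(structure(list(five_prime = empty, three_prime = empty),
                     class = "end_profile"))
  }
  sp <- unlist(range(grl))
  plus <- as.character(GenomicRanges::strand(sp)) == "+"
  five <- ifelse(plus, GenomicRanges::start(sp), GenomicRanges::end(sp))
  three <- ifelse(plus, GenomicRanges::end(sp), GenomicRanges::start(sp))
  structure(list(five_prime = count_positions(five),
                 three_prime = count_positions(three)),
            class = "end_profile")
}
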