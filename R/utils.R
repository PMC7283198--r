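# Internal helpers shared across stages.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Reverse-complement of a plain character string.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Canonical string key of an intron chain
#'
#' Intron chains identify splicing isoforms: two alignments carry the same
#' isoform exactly when all their donor/acceptor pairs coincide. The key is
#' `chrom:strand:start1-end1;start2-end2;...` with introns in genomic order
#' (1-based closed coordinates).
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of intron starts/ends (1-based closed).
#' @return A single character key.
#' @export
intron_chain_key <- function(chrom, strand, starts, ends) {
  o <- order(starts)
  paste0(chrom, ":", strand, ":",
         paste0(starts[o], "-", ends[o], collapse = ";"))
}

# Extract the introns of one alignment's exon blocks (GRanges, sorted).
blocks_to_introns <- function(blocks) {
  if (length(blocks) < 2L) {
    return(GenomicRanges::GRanges())
  }
  sp <- range(blocks)
  IRanges::psetdiff(sp, GenomicRanges::GRangesList(unname(blocks)))[[1L]]
}

# Stop unless all elements of a GRangesList share one chrom and strand.
check_single_track <- function(alns) {
  if (length(alns) == 0L) return(invisible(TRUE))
  u <- unlist(alns, use.names = FALSE)
  if (length(unique(as.character(GenomicRanges::seqnames(u)))) > 1L ||
      length(unique(as.character(GenomicRanges::strand(u)))) > 1L) {
    stop("alignments must share a single chromosome and strand")
  }
  invisible(TRUE)
}

# Named integer vector position -> count from an integer vector of positions.
count_positions <- function(pos) {
  if (length(pos) == 0L) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(pos)
  setNames(as.integer(tab), names(tab))
}
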