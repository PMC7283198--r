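# Read stranding: recover mRNA orientation from terminal poly(A)/poly(T).
#
# Full-length cDNA amplification loses the strand of origin; each molecule is
# sequenced in an arbitrary orientation. A read that still carries its
# poly(A) tail reveals the orientation: poly(A) near the 3' end means the
# read is the sense strand, poly(T) near the 5' end means it is the reverse
# complement. Reads showing neither (tail lost to truncation or degradation)
# or both (likely chimeras) cannot be oriented and are dropped.

#' Tail-detection parameters
#'
#' @param search_window Number of nt scanned at each read end (default 100).
#' @param min_tail_length Minimum homopolymer tract length to accept a tail
#'   (default 10 nt).
#' @param max_mismatch_fraction Maximum fraction of interior mismatches
#'   tolerated inside a tract (default 0.15), absorbing nanopore indels.
#' @param smart_oligo Optional 5'-flank oligo sequence. When supplied, a
#'   poly(A) call additionally requires a fuzzy match (<= 20% edit distance)
#'   of the oligo in the 5' window, and a poly(T) call requires the
#'   reverse-complemented oligo in the 3' window. `NULL` (default) disables
#'   the check.
#' @return An object of class `tail_params`.
#' @export
tail_params <- function(search_window = 100L, min_tail_length = 10L,
                        max_mismatch_fraction = 0.15, smart_oligo = NULL) {
  if (min_tail_length < 1L || search_window < min_tail_length) {
    stop("need search_window >= min_tail_length >= 1")
  }
  if (max_mismatch_fraction < 0 || max_mismatch_fraction > 1) {
    stop("max_mismatch_fraction must lie in [0, 1]")
  }
  structure(list(search_window = as.integer(search_window),
                 min_tail_length = as.integer(min_tail_length),
                 max_mismatch_fraction = max_mismatch_fraction,
                 smart_oligo = smart_oligo),
            class = "tail_params")
}

# Longest tract of `base` within a window (character vector), allowing at
# most floor(max_mismatch_fraction * length) interior mismatches; the tract
# must begin and end with `base`. Returns list(length, start) with length 0
# when no tract exists.
longest_tail_tract <- function(chars, base, max_mismatch_fraction) {
  m <- chars == base
  idx <- which(m)
  if (length(idx) == 0L) return(list(length = 0L, start = NA_integer_))
  cs <- cumsum(m)
  # candidate tracts run from one base position to a later base position
  len <- outer(idx, idx, function(i, j) j - i + 1L)
  match_n <- outer(idx, idx, function(i, j) cs[j] - cs[i] + 1L)
  ok <- len >= 1L & (len - match_n) <= floor(max_mismatch_fraction * len)
  len[!ok] <- 0L
  best <- which.max(len)
  if (len[best] == 0L) return(list(length = 0L, start = NA_integer_))
  list(length = as.integer(len[best]),
       start = idx[(best - 1L) %% length(idx) + 1L])
}

fuzzy_oligo_hit <- function(window_seq, oligo) {
  if (nchar(window_seq) == 0L) return(FALSE)
  hits <- Biostrings::matchPattern(
    oligo, Biostrings::DNAString(window_seq),
    max.mismatch = ceiling(0.2 * nchar(oligo)), with.indels = TRUE)
  length(hits) > 0L
}

#' Detect read orientation from terminal homopolymer tails
#'
#' Scans the last `search_window` nt for a qualifying poly(A) tract and the
#' first `search_window` nt for a qualifying poly(T) tract. A read is
#' `sense` when only the poly(A) qualifies, `antisense` when only the
#' poly(T) qualifies, `ambiguous` when both do (treated as a chimera and
#' discarded downstream), and `none` when neither does.
#'
#' @param sequence A single read sequence (character or DNAString).
#' @param params A [tail_params()].
#' @return A list of class `tail_call` with `orientation` (one of
#'   `"sense"`, `"antisense"`, `"none"`, `"ambiguous"`), `tail_side`
#'   (`"three_prime"`, `"five_prime"`, `"none"`), `tail_length`, and
#'   `tail_start_offset` (0-based distance of the tract from the relevant
#'   read end).
#' @export
detect_orientation <- function(sequence, params = tail_params()) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty read sequence")
  chars <- strsplit(sequence, "")[[1]]
  w <- min(params$search_window, n)
  head_w <- chars[seq_len(w)]
  tail_w <- chars[(n - w + 1L):n]
  a3 <- longest_tail_tract(tail_w, "A", params$max_mismatch_fraction)
  t5 <- longest_tail_tract(head_w, "T", params$max_mismatch_fraction)
  a_ok <- a3$length >= params$min_tail_length
  t_ok <- t5$length >= params$min_tail_length
  if (!is.null(params$smart_oligo)) {
    if (a_ok) {
      a_ok <- fuzzy_oligo_hit(paste0(head_w, collapse = ""), params$smart_oligo)
    }
    if (t_ok) {
      t_ok <- fuzzy_oligo_hit(paste0(tail_w, collapse = ""),
                              revcomp_chr(params$smart_oligo))
    }
  }
  if (a_ok && t_ok) {
    call <- list(orientation = "ambiguous", tail_side = "none",
                 tail_length = 0L, tail_start_offset = NA_integer_)
  } else if (a_ok) {
    call <- list(orientation = "sense", tail_side = "three_prime",
                 tail_length = a3$length,
                 tail_start_offset = w - (a3$start + a3$length - 1L))
  } else if (t_ok) {
    call <- list(orientation = "antisense", tail_side = "five_prime",
                 tail_length = t5$length,
                 tail_start_offset = t5$start - 1L)
  } else {
    call <- list(orientation = "none", tail_side = "none",
                 tail_length = 0L, tail_start_offset = NA_integer_)
  }
  structure(call, class = "tail_call")
}

#' Strand a set of reads
#'
#' Sense reads pass through unchanged; antisense reads are
#' reverse-complemented (with qualities reversed in step). Reads whose
#' orientation cannot be determined (`none`) and double-tailed reads
#' (`ambiguous`) are dropped and counted. The conservation identity
#' `sense + antisense + discarded == input` always holds
#' (`discarded = discarded_none + discarded_ambiguous`).
#'
#' @param reads A `QualityScaledDNAStringSet` (e.g. from
#'   [read_fastq()] or [simulate_reads()]) or a FASTQ file path.
#' @param params A [tail_params()].
#' @return A list of class `stranding_result`: `reads` (stranded
#'   QualityScaledDNAStringSet, all now 3'-poly(A)), `calls` (per-read
#'   data.frame with `read_id`, `orientation`, `tail_length`), and
#'   `report` (data.frame `category`/`count`).
#' @export
strand_reads <- function(reads, params = tail_params()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n <- length(reads)
  orientation <- character(n)
  tail_length <- integer(n)
  seqs <- as.character(reads)
  for (i in seq_len(n)) {
    call <- detect_orientation(seqs[i], params)
    orientation[i] <- call$orientation
    tail_length[i] <- call$tail_length
  }
  keep_sense <- orientation == "sense"
  keep_anti <- orientation == "antisense"
  out_sense <- reads[keep_sense]
  out_anti <- reads[keep_anti]
  if (length(out_anti)) {
    flipped <- Biostrings::reverseComplement(as(out_anti, "DNAStringSet"))
    q <- IRanges::reverse(Biostrings::quality(out_anti))
    out_anti <- Biostrings::QualityScaledDNAStringSet(
      flipped, Biostrings::PhredQuality(as.character(q)))
    names(out_anti) <- names(flipped)
  }
  out <- c(out_sense, out_anti)
  if (length(out)) out <- out[order(match(names(out), names(reads)))]
  report <- data.frame(
    category = c("sense", "antisense", "discarded_none",
                 "discarded_ambiguous", "total"),
    count = c(sum(keep_sense), sum(keep_anti),
              sum(orientation == "none"), sum(orientation == "ambiguous"), n))
  structure(list(reads = out,
                 calls = data.frame(read_id = names(reads),
                                    orientation = orientation,
                                    tail_length = tail_length,
                                    stringsAsFactors = FALSE),
                 report = report),
            class = "stranding_result")
}

#' @export
print.stranding_result <- function(x, ...) {
  cat("stranding_result:\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Read a FASTQ file into a QualityScaledDNAStringSet
#'
#' @param path FASTQ path (gzip transparent).
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # Biostrings warns about dropping (empty) metadata columns on conversion
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

#' Write a QualityScaledDNAStringSet as FASTQ
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeXStringSet(as(reads, "DNAStringSet"), path,
                              format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Write a stranding report as TSV
#'
#' @param result A `stranding_result`.
#' @param path Output path.
#' @export
write_strand_report <- function(result, path) {
  write.table(result$report, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
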