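# Fixture builders and independent brute-force oracles used across tests.
# The oracles are deliberately naive re-implementations (per-position scans,
# exhaustive enumeration) kept separate from the package's algorithms.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# One split alignment as a GRanges of exon blocks.
aln_blocks <- function(chrom, strand, starts, ends) {
  GRanges(chrom, IRanges(starts, ends), strand = strand)
}

# A GRangesList of alignments from a list of block matrices.
aln_set <- function(chrom, strand, block_list, ids = NULL) {
  grl <- GRangesList(lapply(block_list, function(b) {
    aln_blocks(chrom, strand, b[, 1], b[, 2])
  }))
  names(grl) <- if (is.null(ids)) sprintf("r%03d", seq_along(grl)) else ids
  grl
}

# --- oracles ----------------------------------------------------------------

# Maximal runs of depth > threshold, by per-position scan.
brute_segment <- function(depth, threshold) {
  above <- depth > threshold
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(above)) {
    if (above[i] && !in_run) {
      starts <- c(starts, i); in_run <- TRUE
    }
    if (!above[i] && in_run) {
      ends <- c(ends, i - 1L); in_run <- FALSE
    }
  }
  if (in_run) ends <- c(ends, length(above))
  cbind(starts, ends)
}

# Gap-linkage clustering by pairwise scan; returns representative/total per
# cluster in position order.
brute_cluster <- function(site_counts, gap, strand = "+") {
  pos <- sort(as.integer(names(site_counts)))
  if (length(pos) == 0L) return(NULL)
  cl <- list(c(pos[1]))
  for (p in pos[-1]) {
    last <- cl[[length(cl)]]
    if (p - max(last) <= gap) {
      cl[[length(cl)]] <- c(last, p)
    } else {
      cl[[length(cl) + 1L]] <- p
    }
  }
  do.call(rbind, lapply(cl, function(p) {
    k <- site_counts[as.character(p)]
    top <- p[k == max(k)]
    rep_pos <- if (strand == "+") min(top) else max(top)
    data.frame(representative = rep_pos, total_count = sum(k))
  }))
}

# Group alignments by identical intron chains via string keys built
# independently (substring arithmetic on block coordinates).
brute_collapse <- function(block_list) {
  keys <- vapply(block_list, function(b) {
    if (nrow(b) < 2L) return(NA_character_)
    paste(b[-nrow(b), 2] + 1L, b[-1, 1] - 1L, sep = "-", collapse = ";")
  }, character(1))
  table(keys[!is.na(keys)])
}

# Longest ATG..stop span by exhaustive scan over every start position.
brute_orf <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (i in seq_len(max(0L, n - 5L))) {
    if (paste0(chars[i:(i + 2L)], collapse = "") != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      codon <- paste0(chars[j:(j + 2L)], collapse = "")
      if (codon %in% stops) {
        aa <- (j - i) %/% 3L
        if (is.null(best) || aa > best$aa_length) {
          best <- list(start = i, end = j + 2L, aa_length = aa)
        }
        break
      }
      j <- j + 3L
    }
  }
  best
}

# Random nucleotide string free of long A/T runs (so tail calls never fire).
random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
}

# Small cached simulation shared by tests that only need a standard run.
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tg <- generate_genome(genome_spec(seed = 7L))
      sim <- simulate_reads(tg, read_sim_spec(seed = 8L))
      cache <<- list(tg = tg, sim = sim)
    }
    cache
  }
})
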