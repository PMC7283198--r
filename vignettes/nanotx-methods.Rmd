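---
title: "Stranded long-read transcriptome reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stranded long-read transcriptome reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotx)
```

## The problem

Full-length cDNA sequencing on long-read platforms captures each mRNA in a
single read, preserving its isoform structure end to end. Two properties of
the protocol shape everything in this package. First, cDNA amplification
produces both strands of every molecule, so the read's orientation carries
no information about the transcript's strand — but the poly(A) tail does.
Second, in compact genomes most genes are monoexonic and packed tightly,
with genuine overlapping transcription (antisense RNAs inside protein-coding
loci, divergent promoter pairs, tandem genes with overlapping UTRs), so
assembly tools that key only on splice junctions miss most of the
transcriptome. `nanotx` reconstructs transcripts from per-strand coverage
and transcript end sites, with splicing handled by exact intron-chain
collapsing on top.

## Stranding

A read that retained its tail shows a poly(A) tract near the 3' end when it
is the sense strand, or a poly(T) tract near the 5' end when it is the
reverse complement. `detect_orientation()` scans the terminal
`search_window` (default 100 nt) at each end for the longest tract of the
tail base that begins and ends with that base and contains at most
`floor(max_mismatch_fraction * length)` interior mismatches (defaults 0.15
and a 10 nt minimum). The mismatch allowance absorbs the indel-dominated
error profile of nanopore reads; the 10 nt minimum keeps the false-positive
rate on random sequence well below 1% per window. Reads with qualifying
tracts at *both* ends are treated as likely chimeras and discarded as
`ambiguous` rather than guessed at; reads with neither are discarded as
`none`. Only stranded reads feed the downstream stages. An optional
SMART-oligo check (off by default) additionally requires a fuzzy match of
the 5' flank oligo (≤ 20% edit distance) before a tail qualifies, for
libraries where the primer sequences are known and intact.

Antisense reads are reverse-complemented and their quality strings
reversed — qualities are position-bound, so they are never recomputed.

## Transcriptional units and gene boundaries

Coverage is computed per (chromosome, strand) track from the exon blocks of
the split alignments; intronic gaps contribute nothing. This strand
separation is what prevents an antisense RNA from disturbing the model of
its host gene — the two live on different tracks entirely, and tests assert
that adding minus-strand reads never changes plus-strand models.

A transcriptional unit is a maximal run of positions with depth **strictly
greater** than `coverage_threshold` (default 4 reads, matching the
expression cutoff used for the assessment reference; "exceeds" is read
literally). Units may contain several genes. Because full-length reads end
where transcripts end, the 3' ends of one gene pile up in a small region:
`cluster_sites()` joins sorted end positions while consecutive gaps are at
most `cluster_gap` (20 nt) and takes the modal position as the cluster
representative (ties resolved 5'-most on the strand). `split_unit()` cuts a
unit at every internal 3' cluster with at least `min_site_count` (5) reads
lying at least `min_gene_len` (50 nt) from both unit edges: the upstream
gene ends at the representative and the next gene starts at the strongest
5' site downstream of the cut (falling back to the adjacent base). Cuts are
applied in transcription order, so a unit holding three genes resolves with
two cuts.

The thresholds are deliberately of the same order as the coverage
threshold; all are configurable (`default_config()`), and none was tuned
against any particular dataset — they are the package's standing defaults
for ~20×-per-transcript toy data.

## Spliced genes and isoforms

Each spliced alignment *is* an isoform observation: its intron chain (the
ordered donor/acceptor pairs) identifies the isoform exactly, with no
assembly step. `collapse_spliced()` groups alignments by chain identity.
Since coverage segmentation leaves a spliced gene as one unit per exon,
`build_models()` first merges gene intervals connected by any spliced read
into one locus, then decides the locus's structure.

Sequencing errors create spurious chains, but an error is unlikely to recur
at the same coordinates in independent reads. Hence the two filters in
`filter_isoforms()`: an isoform needs more than one supporting read, and at
least `isoform_coverage_fraction` (1/10) of the locus coverage. Locus
coverage is the maximum depth over the locus (the mean would penalise genes
with long low-covered UTRs; a flag-style argument is not offered — callers
can pass whatever scalar they prefer). The accounting identity
`detected = filtered + kept` is attached to every result. Among kept
isoforms sharing a splicing event, `select_major()` picks the
highest-supported chain (ties to the 5'-most donor, then acceptor); minors
go to the alternatives output, and only majors appear in the main models.
Short terminal exons (≤ 30 nt) whose strand-corrected sequence is ≥ 80%
adenine are removed — these are mis-mapped poly(A) tails, and they only ever
appear at transcript ends, which is why interior exons are never touched.

## ORFs, UTR isoforms and uORFs

ORF search runs on stranded (sense) sequence only, scanning the three
forward frames for ATG→{TAA,TAG,TGA} spans; codons containing N match
nothing. `aa_length` excludes the stop codon, and a transcript is a
noncoding candidate when its longest ORF is ≤ 100 aa (strictly "more than
100 amino acids" to qualify as coding). Reconstructed sequence is always
taken from the genome over the alignment blocks (`genome_correct()`), so
ORF calls are immune to read errors.

Alternative 5'-UTR isoforms of an annotated gene are the distinct 5'
positions — with read count strictly above `utr_site_threshold` (4, shared
with the coverage threshold for a single coherent default set) — of
same-strand reads that start at or after the gene start and span the ORF's
first codon; the first-codon requirement keeps truncated fragments from
faking start sites. 3'-UTR isoforms mirror this at the other end. When the
annotation lacks UTRs the gene-boundary constraint is dropped and the
farthest qualifying site estimates the boundary. For each 5' isoform, the
UTR sequence upstream of the main ATG is scanned for uORFs (every ATG with
an in-frame stop inside the UTR; minimal uORF = ATG + stop), and each uORF
records which isoforms contain it — the biologically interesting case being
a uORF present in the long isoform but absent from the short one.

## Quantification

`assign_reads()` gives each read to the gene with the largest block
overlap; equal-overlap ties are discarded as ambiguous rather than split or
double-counted. Strand matching is on by default; the package's own tests
show that on a simulated sense/antisense pair stranded counting reproduces
the per-gene truth exactly while unstranded counting cannot. RPKM follows
the standard closed form, and counts are exported as TSV with the
downstream differential-expression decision rule (|log2FC| > 2, p < 0.05,
applied by external tools such as DESeq2) recorded in the header.

## Assessment

The expressed reference is the set of genes with expression strictly above
the cutoff (default 4). Three levels:

* **isoform** — a predicted chain is correct only if exactly equal to the
  reference gene's chain;
* **transcript** — correct if the model overlaps the reference gene on the
  same strand with each boundary within `tol_frac` (0.4) of the *reference*
  length. The reference is the tolerance base because the rule exists to
  reject artifact fusions, which are oversized on the reference scale; a
  `tol_base = "pred"` option exists. Each reference gene is creditable
  once, so `n_correct` is the number of genes recovered — duplicated models
  beyond the first per gene are tallied by `count_duplicates()`, the
  package's operationalisation of "same gene, slight difference" (the
  definition is not unique; this one is monotone and easy to audit);
* **junction** — exact set intersection of (chrom, donor, acceptor, strand).

Percentages are rounded to the nearest whole percent
(`round(100 * x)`), which is the precision at which such benchmarks are
customarily reported and the precision the acceptance checks use.

## The simulator, and what passing means

`generate_genome()` lays out ~50 genes over two 50 kb chromosomes:
monoexonic and two-exon spliced genes, nested antisense pairs, divergent
(bidirectional-promoter) pairs and same-strand tandem pairs that overlap by
30–60 nt — the last type exists precisely to force two genes into one
coverage unit so unit splitting is exercised. Each spliced gene carries a
designed minor chain (acceptor shifted 9 nt) emitted at
`minor_isoform_fraction` (5%). Genome sequence is uniform random with one
post-processing step: any 10-mer window containing ≥ 9 A or ≥ 9 T is
broken, so transcript-internal sequence can never mimic a tail and the
error-free stranding accuracy property is exact rather than statistical.
Reads are `flank + transcript + poly(A)` (tail ~N(30, 5), ≥ 12 nt),
emitted in uniform random orientation and shuffled order, with
deletion:insertion:substitution at 1:1:1 event rates (indels:substitutions
= 2:1, the nanopore-like profile) and optional whole-tail truncation.

Problem sizes used in the tests and acceptance script: 50 genes,
20 reads/transcript (~1000 reads) for structure recovery; 2000 reads for
the stranding-rate check; 1000 random instances per brute-force oracle.
The error-free run uses the simulator's perfect alignments, so the
recovery result isolates the reconstruction logic from aligner behaviour;
the 10%-error run goes through minimap2 (`-ax splice --secondary=no`) and
checks that transcript-level sensitivity stays at or above 90%.

What the simulator does *not* model: basecaller-specific homopolymer error
structure, RNA degradation gradients (tail truncation is the only 3' bias),
expression heterogeneity across genes (unless `dispersion > 0`),
multi-intron genes, and paralogy/multi-mapping. Perfect recovery on the toy
genome therefore demonstrates the correctness of the algorithms under their
stated assumptions, not field performance on real libraries, where mapping
ambiguity and splice-site wobble dominate the error budget.

## Numerical and degenerate-input conventions

Coordinates are 1-based closed (GenomicRanges) everywhere in memory; BED's
0-based half-open convention exists only on disk via rtracklayer. Empty
inputs return empty, typed results (no NULLs); zero denominators in
assessment reports yield 0 with an `undefined` flag rather than NaN.
Cluster and tie-breaks are always resolved toward the 5' side of the
relevant strand so that reruns are bit-identical; `run_pipeline()` stamps
outputs with the config hash and produces byte-identical files for
identical inputs and configuration.
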