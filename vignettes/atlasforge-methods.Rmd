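---
title: "atlasforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atlasforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic data do and do
not emulate, and the numerical and design choices made where the design
was genuinely open.

# The pipeline and its assumptions

Large tissue expression atlases for livestock species are built from a
common skeleton: alignment-free quantification of hundreds of RNA-Seq
libraries against a reference transcript catalogue; iterative revision of
that catalogue, because draft-genome annotations both omit real
transcripts and contain spurious models; conservative rule-based
promotion of novel transcript models to protein-coding status; and
clustering of the gene-to-gene co-expression network to read tissue
specificity off the data. atlasforge implements that skeleton as reusable
functions and exercises every stage on synthetic data, so the logic is
testable without multi-terabyte downloads.

## Pseudoalignment quantifier

`buildIndex()` stores the forward k-mers of each transcript;
`pseudoalign()` intersects the per-k-mer transcript sets of both mates of
a read pair (mate 2 reverse-complemented, matching the dUTP stranded
protocol in which mate 1 reads the transcript sense strand). K-mers
absent from the index are ignored; a pair whose intersection is empty is
recorded as unassigned, and unassigned read identifiers are kept because
the multi-pass flow treats them as the raw material for novel-model
discovery. This is a deliberately simplified stand-in for production
pseudoaligners: no transcript de Bruijn graph, no skipping heuristics,
no bootstrap. The pipeline only needs the contract — equivalence-class
counts in, abundances out.

The EM in `emAbundances()` works in abundance space. With `alpha` on the
unit simplex and effective length `l~ = max(l - mu_frag + 1, 1)`, the
E-step assigns each class count to members proportional to `alpha/l~`
and the M-step renormalizes. The recorded objective,
`sum_c n_c log(sum_{t in c} alpha_t/l~_t)`, is the quantity this
iteration provably never decreases (a minorize-maximize argument on the
log of a sum); tests assert the monotonicity at every iteration, and an
independent numerical maximization of the same objective pins the fixed
point on small cases. TPM is `(alpha/l~)` renormalized to one million.

Assumptions worth naming: uniform fragment starts (so the effective
length is the count of fragment start positions), a single fixed mean
fragment length (`fragLenMean = 200` nt — no fragment-size distribution
is modeled), and reads long enough to carry informative k-mers
(`k = 31` by default; configurable down to 11 for very short toy
transcripts, odd so no k-mer is its own reverse complement).

## Multi-pass index revision

`reviseIndex()` removes transcripts whose TPM is exactly 0.0 in every
sample — exact zero, not a small threshold, because pseudoalignment
either assigns reads or it does not — plus an externally supplied
low-quality list, and integrates validated novel models.
The low-quality list is data, not algorithm: in real projects it comes
from upstream curation (e.g. reference transcripts that required
modification against their own genome), which cannot be recomputed from
expression data. Every change is logged with a reason
(`all_zero`, `low_quality_flag`, `novel_validated`), and the final
transcript set is reproducible from the draft set plus the log — the
tests replay the log to check this. De-novo assembly of unassigned reads
is out of scope; candidate novel models enter `runMultipass()` as input,
the package's contribution being the retention logic, not the assembler.

## Novel-model validation

`longestOrfsPerExon()` scans all six frames of each exon's genomic
sequence for the longest open reading frame, defined as a maximal
stop-codon-free stretch of whole codons ("stop-to-stop"). No start codon
is required by default because internal exons of a genuine CDS need not
begin with ATG; `requireStartCodon = TRUE` switches to ATG-anchored
ORFs. "Longest" ranks candidates by stop-inclusive extent — a stretch
terminated by a stop codon spans that stop — so a reading frame that
ends properly at a stop is not out-ranked by an open run of equal coding
length in another frame; reported lengths and peptides exclude the stop.
Remaining ties break deterministically (plus strand first, lower frame,
5'-most). Only the standard genetic code is supported (stops TAA, TAG,
TGA).

`validateOrfChain()` applies the four structural criteria exactly and
reports every violated criterion, not just the first. Criterion (c) is
interpreted as: an internal exon's chosen ORF must not be terminated by
a stop codon before the exon end — the ORF may start mid-exon (allowing
for noisy exon boundaries) but must run until the exon ends. Criterion
(b) applies only to the transcript's 3'-most exon.

`filterHomology()` applies the e-value cutoff (1e-25) as a pre-filter on
rows, then the five per-alignment criteria, then the two query-level
requirements (≥ 5 valid alignments, ≥ 1 whitelisted genus). Forbidden
description keywords are matched as case-insensitive substrings;
third-party annotation is approximated by the extra keyword `"TPA:"`,
configurable, because no fully operational rule exists for it. Genus is
parsed from a dedicated column rather than from free-text descriptions,
for deterministic parsing. Relaxing any single threshold can only grow
the retained set; the tests assert this monotonicity.

## Co-expression network and Markov clustering

`tissueAverage()` reduces samples to per-gene per-tissue means — the
data representation the network is built on; correlating replicate-level
samples instead is available by passing the sample-level matrix
directly, but tissue means are the default because the atlas's unit of
interpretation is the tissue. `expressionFilter()` keeps genes whose
mean TPM strictly exceeds 10 in at least one tissue; at the package's
toy scale this filter is rarely binding (a 300-gene panel normalized to
one million TPM puts most genes above 10), which is expected and
harmless — it exists for realistic-scale matrices. `correlationGraph()`
thresholds Pearson correlations at `r >= rMin` (default 0.80; the lncRNA
convention is the same pipeline at 0.9 on a gene subset). Zero-variance
genes have undefined correlations and are excluded and reported rather
than silently dropped. No automatic threshold selection is attempted;
`thresholdScan()` reports the node/edge trade-off and the user chooses,
as atlas projects do empirically.

`mclCluster()` implements MCL from scratch on a dense column-stochastic
matrix: self-loops of weight 1 are added before normalization (standard
MCL practice, needed for convergence), expansion is the matrix square,
inflation the entry-wise power 2.2 followed by column renormalization,
and entries below `pruneThreshold = 1e-5` are zeroed and columns
renormalized. Edge weights (the correlations) are used as transition
weights rather than a binarized adjacency — the graph is weighted, and
weights carry information. Convergence is declared when the largest
entry change falls below `tol = 1e-6`, capped at `maxIter = 200` (a
warning flags non-convergence, and the current matrix is interpreted).
Prune threshold, tolerance and cap are conventional MCL defaults; no
published value governs them. Clusters are read from the limit matrix's
attractor structure; a node attracted to several systems goes to the one
holding more of its column mass, ties to the system with the smallest
member identifier — MCL theory allows overlap but a partition is
reported, matching how clustering front-ends present MCL output.
Inflation controls granularity (larger = finer); the acceptance script
measures cluster counts at 1.5, 2.2 and 4.0 to confirm the monotone
trend. `postprocessClusters()` sets aside clusters under 5 nodes and
numbers the survivors by decreasing size, ties broken by smallest member
identifier for determinism.

Because no established MCL implementation ships in a typical R stack,
correctness is pinned two ways: property tests (disjoint cliques,
symmetric complete graphs, column stochasticity within 1e-9 after every
inflation step, partition coverage) and frozen reference partitions for
twelve planted-module fixture graphs computed by an independently coded
dense-matrix MCL, against which the package's partitions must be
identical.

## Atlas summaries

Detection uses strict `mean TPM > 1` over a tissue's replicates; the
strictness matters at the boundary and the tests pin it. Cluster
profiles are per-tissue means over member genes; the tissue-specificity
label lists tissues by descending mean, truncated at 5 (the depth used
in atlas summary tables), and a cluster whose top tissue holds less than
25 % of its profile mass is labeled "general" — housekeeping-dominated
clusters in real atlases are exactly such flat profiles. Class labels
beyond the mechanical tissue ordering (e.g. "immune", "pathway") are
curator judgments and are not automated.

# The synthetic-data generator

`syntheticDesign()` fixes the study conditions: 300 genes x 10 tissues x
2 replicates by default — large enough for MCL to have structure to
find, small enough for seconds-scale tests; replicate count is a free
parameter because real atlas projects collect replicates "where
possible" rather than uniformly. Five planted modules of 20 genes are
each active in one distinct tissue (500 TPM active vs 0.1 inactive), 20 %
of genes are housekeeping (100 TPM everywhere), and the rest are
unstructured noise genes with their own random log-normal tissue
profiles (meanlog log 2, sdlog 1.5) — present so that the network stage
faces plausible distractors, not just signal. Replicate noise is
multiplicative log-normal (sd 0.1 on the natural-log scale): positive
support and a realistic heavy tail for TPM. Every sample is renormalized
to one million, so planted "means" are expectations up to that
renormalization.

Reads are drawn from transcripts with probability proportional to
abundance times spliced length, uniform fragment start, fragment length
200 truncated to the transcript; mate 1 is the fragment's 5' end on the
sense strand, mate 2 the reverse complement of its 3' end, and the
convention is recorded in the read names. Gene structures are 2-4 exons
of 150-300 nt with 80-200 nt introns on alternating strands; additional
isoforms skip one internal exon. `plantCodingSequences()` rewrites
chosen loci with engineered coding content (stop-free sense frames,
terminal TAA on the last exon, resampled until the engineered ORF is
strictly the longest across all six frames) so that multi-pass tests can
plant candidates that genuinely satisfy the retention criteria.

What the generator does **not** emulate: indel or quality-calibrated
sequencing error (substitutions only), intron-retention artifacts of
total-RNA libraries, fragment-length variation, positional or GC bias,
paralogy (transcripts are random sequence, so cross-gene k-mer collisions
are essentially absent), and realistic dynamic range across tens of
thousands of genes. Passing tests therefore demonstrate that the
*logic* of each stage is correct under its own model — not that the
quantifier is robust to real sequencing artifacts, nor that network
clusters on real data will be as clean as on planted modules, where
active-tissue sets are disjoint by construction.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately small scales:
20,000 read pairs over 60 transcripts for quantifier recovery, 100
random equivalence-class configurations for EM monotonicity, 500-row
homology tables over 40 queries, a 16-gene/4-sample three-pass run with
two planted novel genes, 60-node fixture graphs for the MCL reference
check, and 50 seeded 300-gene designs for planted-module recovery.
These sizes keep the full suite under a minute while leaving each check
statistically meaningful.

Numerical details: EM converges on max |change in alpha| < 1e-8 (cap
1,000 iterations); transcripts shorter than the mean fragment length
clamp their effective length to 1; all-zero equivalence-class input
yields an all-zero table with a warning rather than an error; MCL
column sums are renormalized after inflation and after pruning, and the
per-iteration deviation from 1 is recorded so tests can assert it stays
below 1e-9; ties everywhere (ORF frames, cluster numbering, attractor
assignment) break by fixed deterministic rules so identical inputs give
byte-identical outputs.

# Known limitations

- The quantifier indexes forward k-mers only and assumes the stranded
  protocol; `stranded = FALSE` queries both orientations but no
  orientation-confidence model exists.
- The pseudoaligner's k-mer intersection can in principle assign a pair
  to a transcript containing all its k-mers scattered non-contiguously;
  with realistic k (31) and non-repetitive references this is
  vanishingly rare, and the substring-search oracle in the tests would
  catch it on the synthetic data.
- Dense-matrix MCL scales to a few thousand nodes; atlas-scale graphs
  (tens of thousands of nodes) would need a sparse implementation.
- ORF validation supports only the standard genetic code.
- The homology filter counts alignment rows as printed; multiple HSPs
  against the same subject each count toward the ≥ 5 requirement, since
  nothing in the record distinguishes them reliably.
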