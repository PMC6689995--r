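# atlasforge

Tools for building a tissue gene-expression atlas from bulk RNA-Seq, the
way large livestock atlas projects are built: alignment-free transcript
quantification with an iteratively revised reference, rule-based retention
of novel protein-coding transcript models, and gene co-expression network
analysis with Markov clustering. The package is aimed at researchers who
want the computational skeleton of such an atlas — quantifier, index
revision bookkeeping, model-validation rules, network construction and
atlas summaries — as tested, reusable R functions, exercised end to end on
synthetic data that the package generates itself.

## What the pipeline does

**Quantification.** A k-mer index is built over the reference transcript
set. Each read pair is pseudoaligned: its compatibility set is the
intersection of the per-k-mer transcript sets over both mates (mate 2 is
reverse-complemented under the stranded dUTP convention). Pairs sharing a
compatibility set form an *equivalence class*; abundances are estimated by
EM over class counts. With `α_t` the abundance of transcript `t` on the
unit simplex and `l̃_t = max(l_t − μ_frag + 1, 1)` its effective length,
the E-step distributes each class count `n_c` over its members
proportional to `α_t / l̃_t`, the M-step renormalizes, and the objective

```
L(α) = Σ_c n_c · log( Σ_{t ∈ c} α_t / l̃_t )
```

never decreases. Abundances are reported as transcripts per million,
`TPM_t = (α_t/l̃_t) / Σ_u (α_u/l̃_u) × 10^6`, and summed to gene level.

**Multi-pass index revision.** After a first pass over all samples,
transcripts with TPM exactly 0 in every sample and transcripts on an
externally supplied low-quality list are dropped; quantification is
repeated (second pass). Candidate novel transcript models are then
validated and the retained ones integrated for a third pass. Unassigned
reads are captured per sample at every pass, and every index change is
logged with its reason, so the final transcript set is reproducible from
the draft set plus the revision log.

**Novel-model validation.** For each candidate, the longest ORF of every
exon is found over all six reading frames. The candidate is retained only
if (a) every exon's longest ORF lies on the same strand, (b) the last ORF
terminates in a stop codon rather than running off the exon end, (c) no
internal exon's ORF is cut short by a stop codon, and (d) the
concatenated peptide is ≥ 50 amino acids. Its peptide must additionally
have conservative homology support: ≥ 5 blast alignments with identity
≥ 90 %, coverage ≥ 90 % of the query, length ≥ 50 aa, no gaps, no
forbidden description keywords ("low quality", "hypothetical", "unnamed",
"uncharacterized", "putative", third-party annotation), e-value ≤ 1e-25,
and at least one alignment to a whitelisted genus (*Bison, Bos, Camelus,
Capra, Ovis, Pantholops, Vicugna*).

**Network analysis.** Expression is averaged per gene per tissue; genes
never exceeding 10 TPM in any tissue are dropped; the gene-to-gene Pearson
correlation matrix is thresholded at `r ≥ 0.80` (0.9 for an lncRNA
subset) into a weighted graph; and the Markov cluster algorithm
(expansion 2, inflation 2.2, from scratch) partitions it. Clusters with
fewer than five nodes are set aside; survivors are numbered 1..K by
decreasing size and labeled by their tissue-specificity profile
("tissue03 > tissue04 > ...", or "general" for flat profiles). Detection
summaries count, per gene, the tissues with mean TPM > 1.

**Synthetic data.** `syntheticDesign()` describes a toy study — genes,
tissues, replicates, planted co-expression modules, housekeeping
fraction, log-normal replicate noise — and the package generates from it
a toy genome with multi-exon transcript models, true TPM matrices,
stranded error-free or noisy read pairs, and blast-like homology tables
with per-record truth labels.

## Worked example

```r
library(atlasforge)
library(SummarizedExperiment)

design <- syntheticDesign(nGenes = 60, nTissues = 6, seed = 42,
                          modules = defaultModules(3, 10))
design
#> SyntheticDesign: 60 genes x 6 tissues x 2 replicates
#>   modules: 3 (30 genes) | housekeeping: 12 | noise sd (log): 0.1
#>   seed: 42

gm <- generateGenomeAndModels(design)
se <- simulateExpression(design, gm$models)
txSeqs <- transcriptSequences(gm$genome, gm$models)
geneMap <- transcriptGeneMap(gm$models)

abund <- transcriptAbundances(assay(se, "TPM")[, "tissue01_rep1"], geneMap)
reads <- simulateReads(txSeqs, abund, nPairs = 5000, readLen = 100, seed = 43)
index <- buildIndex(txSeqs, k = 31)
index
#> PseudoIndex: k = 31 | 60 transcripts | 37728 k-mer entries

ec <- pseudoalign(index, reads$r1, reads$r2)
ec
#> EquivalenceClassCounts: 34 classes | 5000 assigned pairs | 0 unassigned | 5000 total

tab <- emAbundances(ec, index)
genes <- summarizeToGenes(tab, geneMap)
cor(assay(se, "TPM")[genes$gene_id, "tissue01_rep1"], genes$tpm,
    method = "spearman")
#> 0.923   # rank agreement between true and estimated gene TPM at 5,000 pairs

tm <- expressionFilter(tissueAverage(se), minTpm = 10)
graph <- correlationGraph(tm, rMin = 0.80)
graph
#> CoexpressionGraph: 60 nodes | 234 edges | r >= 0.8

clusters <- mclCluster(graph, inflation = 2.2, minClusterSize = 5)
clusters
#> ClusterAssignment: 6 clusters (>= 5 nodes) | 5 small clusters set aside | inflation 2.2

head(clusterProfiles(clusters, tm)$summary[, c("cluster_id", "size", "label")], 4)
#>   cluster_id size                                                label
#> 1          1   12 tissue01 > tissue04 > tissue06 > tissue03 > tissue05
#> 2          2   12 tissue05 > tissue06 > tissue04 > tissue02 > tissue03
#> 3          3   10 tissue02 > tissue04 > tissue06 > tissue05 > tissue01
#> 4          4   10 tissue03 > tissue04 > tissue05 > tissue06 > tissue01

plantedRecoveryARI(clusters, geneRoles(design))
#> 1   # the three planted modules are recovered exactly
```

The three largest tissue-specific clusters sit exactly on the planted
modules (top tissues 01, 02, 03); cluster 2 collects housekeeping/noise
genes with a flat profile. `runMultipass()` chains quantification, index
revision and model validation into the three-pass flow; see the methods
vignette (`vignettes/atlasforge-methods.Rmd`) for the full account.

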