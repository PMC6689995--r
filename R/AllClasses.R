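## Central S4 classes. Expression matrices live in SummarizedExperiment
## objects (assay "TPM", colData = sample metadata, rowData = gene
## annotation); transcript models are GRanges of exon rows. The classes
## below cover the containers that have no established Bioconductor
## equivalent.

setOldClass("data.table")

#' SyntheticDesign: parameters of a toy atlas study
#'
#' Describes the synthetic study from which all pipeline inputs are
#' generated: gene panel size, tissue panel, replication, the planted
#' co-expression modules, the housekeeping fraction, and the replicate-level
#' noise. Genes not claimed by a module or the housekeeping set are
#' unstructured noise genes.
#'
#' @slot nGenes total number of genes.
#' @slot nTissues number of tissues in the panel (named
#'   \code{tissue01, tissue02, ...}).
#' @slot replicates biological replicates per tissue.
#' @slot modules data.frame with columns \code{module_id},
#'   \code{n_genes}, \code{tissues} (comma-separated active tissue names),
#'   \code{mean_active_tpm}, \code{mean_inactive_tpm}.
#' @slot housekeepingFraction fraction of genes expressed uniformly across
#'   all tissues.
#' @slot housekeepingMeanTPM expected TPM of a housekeeping gene in every
#'   tissue (before per-sample renormalization).
#' @slot noiseSdLog replicate-level multiplicative noise: standard
#'   deviation on the natural-log TPM scale.
#' @slot transcriptsPerGene transcripts generated per gene.
#' @slot lncRNAFraction fraction of genes annotated with biotype
#'   \code{lncRNA} (taken from the noise-gene tail of the panel).
#' @slot seed integer seed; all generation is deterministic given it.
#' @exportClass SyntheticDesign
setClass("SyntheticDesign", slots = c(
  nGenes = "integer",
  nTissues = "integer",
  replicates = "integer",
  modules = "data.frame",
  housekeepingFraction = "numeric",
  housekeepingMeanTPM = "numeric",
  noiseSdLog = "numeric",
  transcriptsPerGene = "integer",
  lncRNAFraction = "numeric",
  seed = "integer"
))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nTissues < 1L) msg <- c(msg, "nTissues must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "replicates_per_tissue must be >= 1")
  m <- object@modules
  need <- c("module_id", "n_genes", "tissues", "mean_active_tpm",
            "mean_inactive_tpm")
  if (!all(need %in% names(m))) {
    msg <- c(msg, paste("modules must have columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (any(m$mean_active_tpm < 0) || any(m$mean_inactive_tpm < 0))
      msg <- c(msg, "module TPM means must be >= 0")
    nStructured <- sum(m$n_genes) +
      floor(object@housekeepingFraction * object@nGenes)
    if (nStructured > object@nGenes)
      msg <- c(msg, "module gene counts plus housekeeping genes exceed nGenes")
    panel <- sprintf("tissue%02d", seq_len(object@nTissues))
    act <- unlist(strsplit(m$tissues, ",", fixed = TRUE))
    if (!all(act %in% panel))
      msg <- c(msg, paste("module active tissues outside the tissue panel:",
                          paste(setdiff(act, panel), collapse = ", ")))
  }
  if (object@housekeepingFraction < 0 || object@housekeepingFraction > 1)
    msg <- c(msg, "housekeepingFraction must lie in [0,1]")
  if (object@noiseSdLog < 0) msg <- c(msg, "noiseSdLog must be >= 0")
  if (object@transcriptsPerGene < 1L)
    msg <- c(msg, "transcriptsPerGene must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PseudoIndex: k-mer index over a transcript set
#'
#' Strand-aware k-mer lookup table used by [pseudoalign()]. Forward k-mers
#' of every indexable transcript are stored; reads from the antisense mate
#' are reverse-complemented at query time. Transcripts shorter than k are
#' flagged unindexable and excluded from the table.
#'
#' @slot k odd k-mer length in 11..31.
#' @slot kmerTable data.table with columns \code{kmer} (character) and
#'   \code{tx} (integer index into \code{txNames}).
#' @slot txNames transcript identifiers, in index order.
#' @slot txLengths named integer, spliced transcript lengths (nt).
#' @slot effLengths named numeric, effective lengths
#'   \code{max(length - fragLenMean + 1, 1)}.
#' @slot unindexable identifiers of transcripts shorter than k.
#' @slot fragLenMean assumed mean fragment length used for effective
#'   lengths.
#' @exportClass PseudoIndex
setClass("PseudoIndex", slots = c(
  k = "integer",
  kmerTable = "data.table",
  txNames = "character",
  txLengths = "integer",
  effLengths = "numeric",
  unindexable = "character",
  fragLenMean = "numeric"
))

setValidity("PseudoIndex", function(object) {
  msg <- character()
  if (object@k %% 2L == 0L || object@k < 11L || object@k > 31L)
    msg <- c(msg, "k must be odd and in [11, 31]")
  if (!all(c("kmer", "tx") %in% names(object@kmerTable)))
    msg <- c(msg, "kmerTable must have columns kmer, tx")
  if (length(object@txLengths) != length(object@txNames))
    msg <- c(msg, "txLengths must parallel txNames")
  if (any(object@effLengths < 1))
    msg <- c(msg, "effective lengths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EquivalenceClassCounts: pseudoalignment result
#'
#' Read pairs grouped by their transcript-compatibility set. Every pair is
#' either counted under a non-empty class or listed as unassigned with a
#' reason code, so class counts plus unassigned reads always add up to the
#' total pair count.
#'
#' @slot classes list of integer vectors (indices into \code{txNames}),
#'   one per equivalence class.
#' @slot counts integer read-pair count per class.
#' @slot txNames transcript identifiers the indices refer to.
#' @slot unassigned identifiers of unassigned read pairs.
#' @slot unassignedReason reason code per unassigned pair
#'   (\code{"no_compatible_transcript"} or \code{"read_shorter_than_k"}).
#' @slot nPairs total number of read pairs seen.
#' @exportClass EquivalenceClassCounts
setClass("EquivalenceClassCounts", slots = c(
  classes = "list",
  counts = "integer",
  txNames = "character",
  unassigned = "character",
  unassignedReason = "character",
  nPairs = "integer"
))

setValidity("EquivalenceClassCounts", function(object) {
  msg <- character()
  if (length(object@classes) != length(object@counts))
    msg <- c(msg, "classes and counts must be parallel")
  if (any(lengths(object@classes) == 0L))
    msg <- c(msg, "no class may be keyed by the empty transcript set")
  if (sum(object@counts) + length(object@unassigned) != object@nPairs)
    msg <- c(msg, "class counts + unassigned reads must equal total pairs")
  if (length(object@unassigned) != length(object@unassignedReason))
    msg <- c(msg, "unassignedReason must parallel unassigned")
  if (length(msg)) msg else TRUE
})

#' OrfChain: per-exon longest-ORF decomposition of a transcript model
#'
#' For each exon of a candidate transcript model, the longest open reading
#' frame over all six frames of the exon's genomic sequence, together with
#' the peptide concatenated from the translated ORFs in transcript
#' (5' to 3') order.
#'
#' @slot transcriptId transcript identifier.
#' @slot exons data.frame ordered 5' to 3' along the transcript, with
#'   columns \code{exon_rank}, \code{exon_nt} (exon width),
#'   \code{orf_strand} (genomic strand of the longest ORF, NA when the
#'   exon is shorter than one codon), \code{orf_start}/\code{orf_end}
#'   (1-based positions within the exon sequence as read in ORF
#'   direction), \code{orf_nt} (ORF length, a multiple of 3), and
#'   \code{has_terminal_stop} (ORF immediately followed by an in-frame
#'   stop codon, i.e. the ORF was terminated by a stop rather than by the
#'   exon end).
#' @slot peptide concatenated amino-acid string.
#' @exportClass OrfChain
setClass("OrfChain", slots = c(
  transcriptId = "character",
  exons = "data.frame",
  peptide = "character"
))

setValidity("OrfChain", function(object) {
  msg <- character()
  need <- c("exon_rank", "exon_nt", "orf_strand", "orf_start", "orf_end",
            "orf_nt", "has_terminal_stop")
  if (!all(need %in% names(object@exons)))
    msg <- c(msg, paste("exons must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@exons$orf_nt %% 3L != 0L))
      msg <- c(msg, "ORF lengths must be whole codons")
    if (3L * nchar(object@peptide) != sum(object@exons$orf_nt))
      msg <- c(msg, "peptide length must equal the summed translated ORF length")
  }
  if (length(msg)) msg else TRUE
})

#' CoexpressionGraph: thresholded Pearson co-expression graph
#'
#' Undirected weighted graph over genes whose pairwise Pearson correlation
#' of tissue-mean expression profiles reaches the threshold. Each edge is
#' stored once with \code{gene_a < gene_b}. Genes whose profile has zero
#' variance (correlation undefined) are excluded from the node set and
#' reported separately.
#'
#' @slot nodes gene identifiers carried into the graph.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r} (all \code{r >= rMin}).
#' @slot rMin the correlation threshold.
#' @slot zeroVariance genes excluded because their profile is constant.
#' @exportClass CoexpressionGraph
setClass("CoexpressionGraph", slots = c(
  nodes = "character",
  edges = "data.frame",
  rMin = "numeric",
  zeroVariance = "character"
))

setValidity("CoexpressionGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("gene_a", "gene_b", "r") %in% names(e)))
    msg <- c(msg, "edges must have columns gene_a, gene_b, r")
  else if (nrow(e)) {
    if (any(e$r < object@rMin)) msg <- c(msg, "all edge weights must be >= rMin")
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$gene_a >= e$gene_b))
      msg <- c(msg, "edges must be stored once with gene_a < gene_b")
    if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be graph nodes")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: size-ordered MCL clusters
#'
#' A partition of co-expression graph nodes into clusters numbered
#' \code{1..K} by non-increasing size (ties broken by the smallest member
#' identifier), with clusters below the minimum size set aside rather than
#' numbered.
#'
#' @slot clusters named list (\code{"1"}, \code{"2"}, ...) of character
#'   vectors of gene identifiers.
#' @slot small list of the excluded clusters (each below
#'   \code{minClusterSize}).
#' @slot inflation MCL inflation used.
#' @slot minClusterSize minimum retained cluster size.
#' @slot iterations MCL iterations run.
#' @slot converged whether MCL reached its tolerance before the iteration
#'   cap.
#' @slot maxColSumDeviation per-iteration max deviation of the transition
#'   matrix column sums from 1 after inflation.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment", slots = c(
  clusters = "list",
  small = "list",
  inflation = "numeric",
  minClusterSize = "integer",
  iterations = "integer",
  converged = "logical",
  maxColSumDeviation = "numeric"
))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  all_members <- c(unlist(object@clusters), unlist(object@small))
  if (anyDuplicated(all_members))
    msg <- c(msg, "clusters and small sets must be disjoint")
  sz <- lengths(object@clusters)
  if (length(sz) > 1L && any(diff(sz) > 0L))
    msg <- c(msg, "clusters must be ordered by non-increasing size")
  if (length(sz) && any(sz < object@minClusterSize))
    msg <- c(msg, "every retained cluster must reach minClusterSize")
  if (length(msg)) msg else TRUE
})

#' PassResult: one quantification pass over all samples
#'
#' @slot passNumber 1-based pass counter.
#' @slot transcriptTPM SummarizedExperiment, transcripts x samples
#'   (assays \code{TPM} and \code{est_counts}).
#' @slot geneTPM SummarizedExperiment, genes x samples (assay \code{TPM}).
#' @slot unassigned named list (per sample) of unassigned read
#'   identifiers.
#' @slot indexIds transcript identifiers making up this pass's index.
#' @exportClass PassResult
setClass("PassResult", slots = c(
  passNumber = "integer",
  transcriptTPM = "SummarizedExperiment",
  geneTPM = "SummarizedExperiment",
  unassigned = "list",
  indexIds = "character"
))

## ---- show methods ---------------------------------------------------------

setMethod("show", "SyntheticDesign", function(object) {
  cat("SyntheticDesign:", object@nGenes, "genes x", object@nTissues,
      "tissues x", object@replicates, "replicates\n")
  cat("  modules:", nrow(object@modules),
      sprintf("(%d genes)", sum(object@modules$n_genes)),
      "| housekeeping:", floor(object@housekeepingFraction * object@nGenes),
      "| noise sd (log):", object@noiseSdLog, "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "PseudoIndex", function(object) {
  cat("PseudoIndex: k =", object@k, "|", length(object@txNames),
      "transcripts |", nrow(object@kmerTable), "k-mer entries\n")
  if (length(object@unindexable))
    cat("  unindexable (< k nt):", length(object@unindexable), "\n")
})

setMethod("show", "EquivalenceClassCounts", function(object) {
  cat("EquivalenceClassCounts:", length(object@classes), "classes |",
      sum(object@counts), "assigned pairs |", length(object@unassigned),
      "unassigned |", object@nPairs, "total\n")
})

setMethod("show", "OrfChain", function(object) {
  cat("OrfChain for", object@transcriptId, ":", nrow(object@exons),
      "exons | peptide", nchar(object@peptide), "aa\n")
})

setMethod("show", "CoexpressionGraph", function(object) {
  cat("CoexpressionGraph:", length(object@nodes), "nodes |",
      nrow(object@edges), "edges | r >=", object@rMin, "\n")
  if (length(object@zeroVariance))
    cat("  zero-variance genes excluded:", length(object@zeroVariance), "\n")
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@clusters), "clusters (>=",
      object@minClusterSize, "nodes) |", length(object@small),
      "small clusters set aside | inflation", object@inflation, "\n")
})

setMethod("show", "PassResult", function(object) {
  cat("PassResult: pass", object@passNumber, "|",
      length(object@indexIds), "transcripts in index |",
      ncol(object@transcriptTPM), "samples\n")
})
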