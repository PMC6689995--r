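## Accessor generics and methods. Slot access stays internal; user code
## goes through these.

#' Equivalence classes as a named count vector
#'
#' @param x an \linkS4class{EquivalenceClassCounts} object.
#' @return named integer vector; names are comma-joined sorted transcript
#'   identifiers, values are read-pair counts.
#' @export
setGeneric("ecClasses", function(x) standardGeneric("ecClasses"))

#' @rdname ecClasses
#' @export
setMethod("ecClasses", "EquivalenceClassCounts", function(x) {
  keys <- vapply(x@classes, function(m)
    paste(sort(x@txNames[m]), collapse = ","), character(1))
  setNames(x@counts, keys)
})

#' Unassigned read identifiers with reason codes
#'
#' @param x an \linkS4class{EquivalenceClassCounts} object.
#' @return data.frame with columns \code{read_id}, \code{reason}.
#' @export
setGeneric("unassignedReads", function(x) standardGeneric("unassignedReads"))

#' @rdname unassignedReads
#' @export
setMethod("unassignedReads", "EquivalenceClassCounts", function(x) {
  data.frame(read_id = x@unassigned, reason = x@unassignedReason,
             stringsAsFactors = FALSE)
})

#' Retained clusters of a ClusterAssignment
#'
#' @param x a \linkS4class{ClusterAssignment} object.
#' @return named list of character vectors, numbered by decreasing size.
#' @export
setGeneric("clusterSets", function(x) standardGeneric("clusterSets"))

#' @rdname clusterSets
#' @export
setMethod("clusterSets", "ClusterAssignment", function(x) x@clusters)

#' Clusters set aside for falling below the minimum size
#'
#' @param x a \linkS4class{ClusterAssignment} object.
#' @return list of character vectors.
#' @export
setGeneric("smallClusters", function(x) standardGeneric("smallClusters"))

#' @rdname smallClusters
#' @export
setMethod("smallClusters", "ClusterAssignment", function(x) x@small)

#' Cluster membership as a named vector
#'
#' @param x a \linkS4class{ClusterAssignment} object.
#' @return named integer vector mapping each clustered gene to its cluster
#'   number; genes in set-aside small clusters get \code{NA}.
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname clusterMembership
#' @export
setMethod("clusterMembership", "ClusterAssignment", function(x) {
  m <- integer(0)
  if (length(x@clusters)) {
    m <- rep.int(seq_along(x@clusters), lengths(x@clusters))
    names(m) <- unlist(x@clusters, use.names = FALSE)
  }
  sm <- unlist(x@small, use.names = FALSE)
  if (length(sm)) m <- c(m, setNames(rep.int(NA_integer_, length(sm)), sm))
  m
})

#' Tissue panel of a synthetic design
#'
#' @param design a \linkS4class{SyntheticDesign} object.
#' @return character vector \code{tissue01, tissue02, ...}.
#' @export
tissuePanel <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  sprintf("tissue%02d", seq_len(design@nTissues))
}

#' Graph edge table
#'
#' @param x a \linkS4class{CoexpressionGraph} object.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}, \code{r}.
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "CoexpressionGraph", function(x) x@edges)

#' Graph node identifiers
#'
#' @param x a \linkS4class{CoexpressionGraph} object.
#' @return character vector of gene identifiers.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "CoexpressionGraph", function(x) x@nodes)

#' ORF table of an OrfChain
#'
#' @param x an \linkS4class{OrfChain} object.
#' @return the per-exon ORF data.frame, ordered 5' to 3' along the
#'   transcript.
#' @export
setGeneric("orfTable", function(x) standardGeneric("orfTable"))

#' @rdname orfTable
#' @export
setMethod("orfTable", "OrfChain", function(x) x@exons)

#' Concatenated peptide of an OrfChain
#'
#' @param x an \linkS4class{OrfChain} object.
#' @return single amino-acid string.
#' @export
setGeneric("chainPeptide", function(x) standardGeneric("chainPeptide"))

#' @rdname chainPeptide
#' @export
setMethod("chainPeptide", "OrfChain", function(x) x@peptide)

#' Gene-level TPM matrix of a quantification pass
#'
#' @param x a \linkS4class{PassResult} object.
#' @return SummarizedExperiment (genes x samples, assay \code{TPM}).
#' @export
setGeneric("geneTPM", function(x) standardGeneric("geneTPM"))

#' @rdname geneTPM
#' @export
setMethod("geneTPM", "PassResult", function(x) x@geneTPM)

#' Transcript-level TPM matrix of a quantification pass
#'
#' @param x a \linkS4class{PassResult} object.
#' @return SummarizedExperiment (transcripts x samples, assays \code{TPM},
#'   \code{est_counts}).
#' @export
setGeneric("transcriptTPM", function(x) standardGeneric("transcriptTPM"))

#' @rdname transcriptTPM
#' @export
setMethod("transcriptTPM", "PassResult", function(x) x@transcriptTPM)
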