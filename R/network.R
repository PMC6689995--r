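#' Average expression per gene per tissue
#'
#' Arithmetic mean of TPM over each tissue's replicate samples. Tissue
#' column order follows first appearance in the sample metadata, which is
#' how organ-system ordering is conveyed.
#'
#' @param expression SummarizedExperiment with a \code{TPM} assay and a
#'   tissue column in \code{colData}, or a plain matrix plus
#'   \code{metadata}.
#' @param metadata optional data.frame with columns \code{sample},
#'   \code{tissue}; required when \code{expression} is a matrix.
#' @param tissueColumn name of the tissue column (default
#'   \code{"tissue"}).
#' @return numeric matrix, genes x tissues.
#' @export
tissueAverage <- function(expression, metadata = NULL,
                          tissueColumn = "tissue") {
  if (is(expression, "SummarizedExperiment")) {
    mat <- assay(expression, "TPM")
    tissues <- as.character(colData(expression)[[tissueColumn]])
  } else {
    mat <- as.matrix(expression)
    if (is.null(metadata)) stop("metadata is required for matrix input")
    m <- match(colnames(mat), metadata$sample)
    if (anyNA(m))
      stop("sample(s) without a tissue label: ",
           paste(colnames(mat)[is.na(m)], collapse = ", "))
    tissues <- as.character(metadata[[tissueColumn]][m])
  }
  if (anyNA(tissues) || any(tissues == ""))
    stop("sample(s) without a tissue label: ",
         paste(colnames(mat)[is.na(tissues) | tissues == ""], collapse = ", "))
  lev <- unique(tissues)
  out <- vapply(lev, function(t)
    rowMeans(mat[, tissues == t, drop = FALSE]), numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), lev))
}

#' Drop genes never averaging above a TPM floor
#'
#' A gene is kept when its mean TPM exceeds \code{minTpm} in at least one
#' tissue (strict inequality). Row order is preserved.
#'
#' @param tissueMatrix genes x tissues matrix from [tissueAverage()].
#' @param minTpm the floor (default 10).
#' @return the row subset of \code{tissueMatrix}.
#' @export
expressionFilter <- function(tissueMatrix, minTpm = 10) {
  if (minTpm < 0) stop("minTpm must be >= 0")
  keep <- apply(tissueMatrix, 1L, max) > minTpm
  if (!any(keep))
    stop("no gene exceeds minTpm = ", minTpm,
         " in any tissue; lower the threshold")
  tissueMatrix[keep, , drop = FALSE]
}

#' Thresholded Pearson co-expression graph
#'
#' Pearson correlation of every gene pair's tissue-profile vectors; an
#' edge is kept when \code{r >= rMin}. Genes with a constant profile
#' (zero variance, correlation undefined) are excluded from the node set
#' and reported in the \code{zeroVariance} slot.
#'
#' @param tissueMatrix genes x tissues matrix (post-filter).
#' @param rMin correlation threshold in (0, 1].
#' @return a \linkS4class{CoexpressionGraph}.
#' @export
correlationGraph <- function(tissueMatrix, rMin = 0.80) {
  if (rMin <= 0 || rMin > 1) stop("rMin must lie in (0, 1]")
  if (ncol(tissueMatrix) < 3L) stop("at least 3 tissues are required")
  sds <- apply(tissueMatrix, 1L, sd)
  zv <- rownames(tissueMatrix)[sds == 0]
  tm <- tissueMatrix[sds > 0, , drop = FALSE]
  if (nrow(tm) < 2L) stop("fewer than 2 genes with variable profiles")
  cc <- cor(t(tm))
  idx <- which(upper.tri(cc) & cc >= rMin, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(cc)[idx[, 1L]],
                      gene_b = rownames(cc)[idx[, 2L]],
                      r = cc[idx], stringsAsFactors = FALSE)
  flip <- edges$gene_a > edges$gene_b
  if (any(flip)) {
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("CoexpressionGraph", nodes = rownames(tm), edges = edges,
      rMin = rMin, zeroVariance = zv)
}

#' Node/edge counts over a range of correlation thresholds
#'
#' Reports, for each candidate threshold, how many genes keep at least
#' one edge and how many edges survive — the trade-off practitioners
#' inspect when choosing a threshold empirically. No automatic choice is
#' made.
#'
#' @param tissueMatrix genes x tissues matrix (post-filter).
#' @param thresholds candidate values of \code{rMin}.
#' @return data.frame with columns \code{r_min}, \code{n_nodes_connected},
#'   \code{n_edges}.
#' @export
thresholdScan <- function(tissueMatrix, thresholds = seq(0.7, 0.95, 0.05)) {
  sds <- apply(tissueMatrix, 1L, sd)
  tm <- tissueMatrix[sds > 0, , drop = FALSE]
  cc <- cor(t(tm))
  ut <- cc[upper.tri(cc)]
  ii <- which(upper.tri(cc), arr.ind = TRUE)
  do.call(rbind, lapply(thresholds, function(th) {
    keep <- ut >= th
    data.frame(r_min = th,
               n_nodes_connected = length(unique(c(ii[keep, 1L], ii[keep, 2L]))),
               n_edges = sum(keep))
  }))
}

#' Export a co-expression graph
#'
#' Writes the edge list as TSV and, when cluster membership is supplied,
#' a GraphML file with the cluster number as a node attribute.
#'
#' @param graph a \linkS4class{CoexpressionGraph}.
#' @param edgeFile path for the edge-list TSV (\code{gene_a},
#'   \code{gene_b}, \code{r}).
#' @param graphmlFile optional path for a GraphML export.
#' @param clusters optional \linkS4class{ClusterAssignment} whose
#'   membership is attached to the GraphML nodes.
#' @return invisibly, the paths written.
#' @export
writeGraph <- function(graph, edgeFile, graphmlFile = NULL,
                       clusters = NULL) {
  utils::write.table(graph@edges, edgeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- edgeFile
  if (!is.null(graphmlFile)) {
    g <- graph_from_data_frame(graph@edges, directed = FALSE,
                               vertices = data.frame(name = graph@nodes))
    if (!is.null(clusters)) {
      mem <- clusterMembership(clusters)
      g <- set_vertex_attr(g, "cluster",
                           value = as.integer(mem[graph@nodes]))
    }
    write_graph(g, graphmlFile, format = "graphml")
    written <- c(written, graphmlFile)
  }
  invisible(written)
}
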