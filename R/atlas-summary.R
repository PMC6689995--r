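#' Per-tissue detection statistics and per-gene tissue breadth
#'
#' A gene counts as detected in a tissue when its mean TPM over that
#' tissue's replicate samples is strictly greater than \code{threshold}
#' (default 1). Per-gene breadth is the number of tissues with
#' detection; per-tissue counts come with the fraction of protein-coding
#' genes detected.
#'
#' @param expression SummarizedExperiment with a \code{TPM} assay,
#'   a \code{tissue} column in \code{colData} and a \code{biotype}
#'   column in \code{rowData}.
#' @param threshold detection TPM floor, strict (default 1).
#' @return list with \code{perTissue} (data.frame \code{tissue},
#'   \code{n_detected}, \code{frac_protein_coding}), \code{perGene}
#'   (data.frame \code{gene_id}, \code{n_tissues_detected}),
#'   \code{detected} (logical genes x tissues matrix) and
#'   \code{threshold}.
#' @export
detectionSummary <- function(expression, threshold = 1) {
  stopifnot(is(expression, "SummarizedExperiment"))
  bt <- rowData(expression)$biotype
  if (is.null(bt)) stop("rowData must carry a biotype column")
  known <- c("protein_coding", "lncRNA", "other")
  if (any(!bt %in% known)) {
    warning("unknown biotype value(s) treated as 'other': ",
            paste(unique(bt[!bt %in% known]), collapse = ", "))
    bt[!bt %in% known] <- "other"
  }
  tm <- tissueAverage(expression)
  detected <- tm > threshold
  pc <- bt == "protein_coding"
  perTissue <- data.frame(
    tissue = colnames(detected),
    n_detected = colSums(detected),
    frac_protein_coding = if (any(pc))
      colSums(detected[pc, , drop = FALSE]) / sum(pc) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  perGene <- data.frame(gene_id = rownames(detected),
                        n_tissues_detected = rowSums(detected),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(perTissue = perTissue, perGene = perGene, detected = detected,
       threshold = threshold)
}

#' Mean expression profiles and tissue-specificity labels per cluster
#'
#' The profile of a cluster is the per-tissue arithmetic mean over its
#' member genes. The specificity label lists tissues by descending mean
#' ("tissue03 > tissue07 > ..."), truncated at \code{labelDepth}; a
#' cluster whose top tissue holds less than \code{generalShare} of the
#' profile mass is labeled \code{"general"}.
#'
#' @param assignment a \linkS4class{ClusterAssignment}.
#' @param tissueMatrix genes x tissues matrix covering every clustered
#'   gene.
#' @param labelDepth tissues listed in the label (default 5).
#' @param generalShare top-tissue share below which a cluster is called
#'   general (default 0.25).
#' @return list with \code{profiles} (clusters x tissues matrix of mean
#'   TPM) and \code{summary} (data.frame \code{cluster_id}, \code{size},
#'   \code{top_tissue}, \code{top_tissue_share}, \code{label}).
#' @export
clusterProfiles <- function(assignment, tissueMatrix, labelDepth = 5L,
                            generalShare = 0.25) {
  cl <- clusterSets(assignment)
  if (!length(cl))
    return(list(profiles = matrix(0, 0, ncol(tissueMatrix),
                                  dimnames = list(NULL, colnames(tissueMatrix))),
                summary = data.frame(cluster_id = integer(0), size = integer(0),
                                     top_tissue = character(0),
                                     top_tissue_share = numeric(0),
                                     label = character(0))))
  missing <- setdiff(unlist(cl), rownames(tissueMatrix))
  if (length(missing))
    stop("clustered gene(s) absent from the tissue matrix: ",
         paste(head(missing, 5), collapse = ", "))
  profiles <- t(vapply(cl, function(g)
    colMeans(tissueMatrix[g, , drop = FALSE]), numeric(ncol(tissueMatrix))))
  rownames(profiles) <- names(cl)
  summ <- do.call(rbind, lapply(names(cl), function(id) {
    p <- profiles[id, ]
    ord <- order(-p, colnames(profiles))
    share <- if (sum(p) > 0) max(p) / sum(p) else 0
    lab <- if (share < generalShare) "general" else
      paste(colnames(profiles)[head(ord, labelDepth)], collapse = " > ")
    data.frame(cluster_id = as.integer(id), size = length(cl[[id]]),
               top_tissue = colnames(profiles)[ord[1L]],
               top_tissue_share = share, label = lab,
               stringsAsFactors = FALSE)
  }))
  list(profiles = profiles, summary = summ)
}

#' Write the atlas deliverables to a directory
#'
#' Writes \code{atlas.tsv} (gene rows, per-sample TPM columns, and the
#' per-gene tissue-breadth column \code{"Expression summary"}),
#' \code{samples.tsv}, \code{detection_per_tissue.tsv},
#' \code{clusters.tsv} (cluster membership; header only when there are
#' no clusters) and \code{cluster_summary.tsv}. All files round-trip
#' through [readAtlasTable()].
#'
#' @param expression SummarizedExperiment with a \code{TPM} assay.
#' @param detection result of [detectionSummary()] on the same object.
#' @param clusters a \linkS4class{ClusterAssignment} or NULL.
#' @param outdir output directory.
#' @param force overwrite an existing atlas (default FALSE).
#' @return invisibly, the paths written.
#' @export
exportAtlas <- function(expression, detection, clusters, outdir,
                        force = FALSE) {
  atlasFile <- file.path(outdir, "atlas.tsv")
  if (file.exists(atlasFile) && !force)
    stop("output exists (", atlasFile, "); use force = TRUE to overwrite")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  tpm <- assay(expression, "TPM")
  breadth <- detection$perGene$n_tissues_detected[
    match(rownames(tpm), detection$perGene$gene_id)]
  atlas <- data.frame(gene_id = rownames(tpm), tpm,
                      check.names = FALSE, stringsAsFactors = FALSE)
  atlas[["Expression summary"]] <- breadth
  write.table(atlas, atlasFile, sep = "\t", quote = FALSE,
              row.names = FALSE)

  write.table(as.data.frame(colData(expression)),
              file.path(outdir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(detection$perTissue,
              file.path(outdir, "detection_per_tissue.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  memb <- if (!is.null(clusters)) {
    m <- clusterMembership(clusters)
    m <- m[!is.na(m)]
    data.frame(cluster_id = unname(m), gene_id = names(m))
  } else data.frame(cluster_id = integer(0), gene_id = character(0))
  memb <- memb[order(memb$cluster_id, memb$gene_id), , drop = FALSE]
  write.table(memb, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sizes <- if (nrow(memb)) as.data.frame(table(memb$cluster_id),
                                         stringsAsFactors = FALSE)
           else data.frame(Var1 = character(0), Freq = integer(0))
  names(sizes) <- c("cluster_id", "size")
  write.table(sizes, file.path(outdir, "cluster_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file.path(outdir, c("atlas.tsv", "samples.tsv",
                                "detection_per_tissue.tsv", "clusters.tsv",
                                "cluster_summary.tsv")))
}

#' Read an exported atlas back
#'
#' @param outdir directory written by [exportAtlas()].
#' @return list with \code{expression} (SummarizedExperiment, assay
#'   \code{TPM}, sample metadata restored), \code{breadth} (named
#'   per-gene tissue counts) and \code{clusters} (membership
#'   data.frame).
#' @export
readAtlasTable <- function(outdir) {
  atlas <- read.delim(file.path(outdir, "atlas.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
  samples <- read.delim(file.path(outdir, "samples.tsv"),
                        stringsAsFactors = FALSE)
  breadth <- setNames(atlas[["Expression summary"]], atlas$gene_id)
  tpm <- as.matrix(atlas[, setdiff(names(atlas),
                                   c("gene_id", "Expression summary")),
                         drop = FALSE])
  rownames(tpm) <- atlas$gene_id
  se <- SummarizedExperiment(
    assays = list(TPM = tpm),
    colData = DataFrame(samples, row.names = samples$sample))
  clusters <- read.delim(file.path(outdir, "clusters.tsv"),
                         stringsAsFactors = FALSE)
  list(expression = se, breadth = breadth, clusters = clusters)
}
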