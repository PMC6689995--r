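#' Expected per-tissue mean expression implied by a design
#'
#' Builds the gene-by-tissue matrix of expected TPM before replicate
#' noise and per-sample renormalization: module genes take their module's
#' active/inactive means, housekeeping genes a constant mean in every
#' tissue, and noise genes an unstructured log-normal profile drawn once
#' per gene-tissue pair from the design seed (part of the ground truth,
#' not replicate noise).
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @return numeric matrix, genes x tissues.
#' @export
expectedTissueMeans <- function(design) {
  roles <- geneRoles(design)
  tissues <- tissuePanel(design)
  E <- matrix(0, nrow = design@nGenes, ncol = design@nTissues,
              dimnames = list(roles$gene_id, tissues))
  withSeed(design@seed + 1000L, {
    for (m in seq_len(nrow(design@modules))) {
      mid <- design@modules$module_id[m]
      act <- strsplit(design@modules$tissues[m], ",", fixed = TRUE)[[1L]]
      if (!all(act %in% tissues))
        stop("module ", mid, " names tissue(s) outside the panel: ",
             paste(setdiff(act, tissues), collapse = ", "))
      g <- roles$gene_id[which(!is.na(roles$module_id) & roles$module_id == mid)]
      E[g, ] <- design@modules$mean_inactive_tpm[m]
      E[g, act] <- design@modules$mean_active_tpm[m]
    }
    hk <- roles$gene_id[roles$role == "housekeeping"]
    E[hk, ] <- design@housekeepingMeanTPM
    nz <- roles$gene_id[roles$role == "noise"]
    if (length(nz))
      E[nz, ] <- matrix(rlnorm(length(nz) * design@nTissues,
                               meanlog = log(2), sdlog = 1.5),
                        nrow = length(nz))
  })
  E
}

#' Simulate a replicate-level true TPM matrix
#'
#' For each tissue and replicate, multiplies the expected tissue means by
#' i.i.d. log-normal noise (sd \code{noiseSdLog} on the natural-log
#' scale) and renormalizes each sample to sum to one million, the TPM
#' convention. With zero noise all replicates of a tissue are identical.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @param models optional exon-level \code{GRanges}; when supplied, the
#'   gene panel is checked against the models' gene identifiers.
#' @return \code{SummarizedExperiment} (assay \code{TPM}, genes x
#'   samples) with sample metadata in \code{colData} (\code{sample},
#'   \code{tissue}, \code{replicate}, \code{animal}, \code{sex},
#'   \code{library_type}) and gene roles in \code{rowData}. The expected
#'   tissue-mean matrix is stored in \code{metadata()$expectedMeans}.
#' @export
simulateExpression <- function(design, models = NULL) {
  E <- expectedTissueMeans(design)
  roles <- geneRoles(design)
  if (!is.null(models)) {
    mg <- unique(mcols(models)$gene_id)
    if (!setequal(mg, roles$gene_id))
      stop("models gene panel does not match the design")
  }
  tissues <- tissuePanel(design)
  nrep <- design@replicates
  samples <- as.vector(t(outer(tissues, seq_len(nrep),
                               function(t, r) sprintf("%s_rep%d", t, r))))
  tissueOf <- rep(tissues, each = nrep)
  repOf <- rep(seq_len(nrep), times = length(tissues))

  tpm <- matrix(0, nrow = design@nGenes, ncol = length(samples),
                dimnames = list(roles$gene_id, samples))
  withSeed(design@seed + 2000L, {
    for (j in seq_along(samples)) {
      noise <- exp(rnorm(design@nGenes, mean = 0, sd = design@noiseSdLog))
      tpm[, j] <- E[, tissueOf[j]] * noise
    }
  })
  tpm <- normalizeTPM(tpm)

  cd <- DataFrame(sample = samples, tissue = tissueOf, replicate = repOf,
                  animal = sprintf("animal%02d", repOf),
                  sex = ifelse(repOf %% 2L == 1L, "male", "female"),
                  library_type = "mRNA", row.names = samples)
  rd <- DataFrame(roles, row.names = roles$gene_id)
  se <- SummarizedExperiment(assays = list(TPM = tpm), colData = cd,
                             rowData = rd)
  metadata(se)$expectedMeans <- E
  metadata(se)$design <- design
  se
}

#' Split gene abundances evenly over member transcripts
#'
#' @param geneTPM named numeric vector of gene TPM values.
#' @param geneMap named character vector mapping transcript_id to
#'   gene_id (see [transcriptGeneMap()]).
#' @return named numeric vector of transcript TPM values covering every
#'   transcript in \code{geneMap}.
#' @export
transcriptAbundances <- function(geneTPM, geneMap) {
  nTx <- table(geneMap)
  miss <- setdiff(unname(geneMap), names(geneTPM))
  if (length(miss))
    stop("genes without TPM values: ", paste(head(miss, 5), collapse = ", "))
  out <- geneTPM[unname(geneMap)] / as.numeric(nTx[unname(geneMap)])
  setNames(as.numeric(out), names(geneMap))
}
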