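#' Describe a synthetic atlas study
#'
#' Constructs a \linkS4class{SyntheticDesign}: the full parameterization of
#' a toy tissue atlas with planted co-expression structure. The defaults
#' describe a panel of 300 genes over 10 tissues with 2 replicates each:
#' five 20-gene modules, each active in a single distinct tissue, a 20%
#' housekeeping fraction expressed uniformly everywhere, and the remaining
#' genes as unstructured noise. Replicate-level noise is multiplicative
#' log-normal.
#'
#' @param nGenes total number of genes (>= 1).
#' @param nTissues number of tissues; the panel is named
#'   \code{tissue01..tissueNN}.
#' @param replicates biological replicates per tissue (>= 1).
#' @param modules data.frame describing the planted modules (columns
#'   \code{module_id}, \code{n_genes}, \code{tissues} as comma-separated
#'   active tissue names, \code{mean_active_tpm}, \code{mean_inactive_tpm});
#'   \code{NULL} builds the default five disjoint single-tissue modules.
#' @param housekeepingFraction fraction of genes expressed uniformly in
#'   every tissue.
#' @param housekeepingMeanTPM expected TPM of a housekeeping gene.
#' @param noiseSdLog replicate noise sd on the natural-log TPM scale.
#' @param transcriptsPerGene transcripts generated per gene.
#' @param lncRNAFraction fraction of genes (taken from the noise tail)
#'   annotated with biotype \code{lncRNA}.
#' @param seed integer seed controlling all downstream generation.
#' @return a validated \linkS4class{SyntheticDesign}.
#' @examples
#' d <- syntheticDesign(nGenes = 50, nTissues = 6, seed = 7,
#'                      modules = defaultModules(3, 10))
#' d
#' @export
syntheticDesign <- function(nGenes = 300L, nTissues = 10L, replicates = 2L,
                            modules = NULL, housekeepingFraction = 0.2,
                            housekeepingMeanTPM = 100,
                            noiseSdLog = 0.1, transcriptsPerGene = 1L,
                            lncRNAFraction = 0.1, seed = 1L) {
  if (nGenes < 1L) stop("nGenes must be >= 1")
  if (is.null(modules)) modules <- defaultModules(5L, 20L)
  new("SyntheticDesign",
      nGenes = as.integer(nGenes), nTissues = as.integer(nTissues),
      replicates = as.integer(replicates), modules = modules,
      housekeepingFraction = housekeepingFraction,
      housekeepingMeanTPM = housekeepingMeanTPM,
      noiseSdLog = noiseSdLog,
      transcriptsPerGene = as.integer(transcriptsPerGene),
      lncRNAFraction = lncRNAFraction, seed = as.integer(seed))
}

#' Default planted-module specification
#'
#' Each module is active in exactly one tissue (module m in tissue m), so
#' active tissue sets are disjoint and between-module correlation is
#' expected to be low.
#'
#' @param nModules number of modules.
#' @param genesPerModule member genes per module.
#' @param meanActiveTPM expected TPM of a member gene in the active
#'   tissue.
#' @param meanInactiveTPM expected TPM elsewhere.
#' @return data.frame suitable for the \code{modules} slot of a design.
#' @export
defaultModules <- function(nModules = 5L, genesPerModule = 20L,
                           meanActiveTPM = 500, meanInactiveTPM = 0.1) {
  data.frame(
    module_id = sprintf("module%02d", seq_len(nModules)),
    n_genes = as.integer(genesPerModule),
    tissues = sprintf("tissue%02d", seq_len(nModules)),
    mean_active_tpm = meanActiveTPM,
    mean_inactive_tpm = meanInactiveTPM,
    stringsAsFactors = FALSE
  )
}

#' Gene roles implied by a design
#'
#' Role assignment is deterministic: module member genes come first (in
#' module order), then housekeeping genes, then unstructured noise genes.
#' The lncRNA biotype is assigned to the tail of the noise genes; all
#' other genes are protein_coding.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{role}
#'   (\code{module}/\code{housekeeping}/\code{noise}), \code{module_id}
#'   (NA outside modules), \code{biotype}.
#' @export
geneRoles <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  n <- design@nGenes
  gene_id <- padId("gene", seq_len(n))
  role <- rep("noise", n)
  module_id <- rep(NA_character_, n)
  idx <- 1L
  for (m in seq_len(nrow(design@modules))) {
    k <- design@modules$n_genes[m]
    role[idx:(idx + k - 1L)] <- "module"
    module_id[idx:(idx + k - 1L)] <- design@modules$module_id[m]
    idx <- idx + k
  }
  nHK <- floor(design@housekeepingFraction * n)
  if (nHK > 0L) role[idx:(idx + nHK - 1L)] <- "housekeeping"
  biotype <- rep("protein_coding", n)
  nLnc <- floor(design@lncRNAFraction * n)
  if (nLnc > 0L) {
    noiseIdx <- which(role == "noise")
    lncIdx <- utils::tail(noiseIdx, nLnc)
    biotype[lncIdx] <- "lncRNA"
  }
  data.frame(gene_id = gene_id, role = role, module_id = module_id,
             biotype = biotype, stringsAsFactors = FALSE)
}
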