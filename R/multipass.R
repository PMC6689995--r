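#' Describe one index revision
#'
#' @param dropAllZero remove transcripts whose TPM is exactly zero in
#'   every sample (default TRUE).
#' @param lowQualityIds externally supplied identifiers flagged as
#'   low-quality predictions; must be a subset of the current index.
#' @param novelIds identifiers of validated novel transcript models to
#'   integrate; must be disjoint from the current index.
#' @param passNumber the pass this revision prepares (informational).
#' @return list of class \code{IndexRevisionPlan}.
#' @export
indexRevisionPlan <- function(dropAllZero = TRUE,
                              lowQualityIds = character(0),
                              novelIds = character(0),
                              passNumber = 1L) {
  structure(list(dropAllZero = dropAllZero,
                 lowQualityIds = lowQualityIds,
                 novelIds = novelIds,
                 passNumber = as.integer(passNumber)),
            class = "IndexRevisionPlan")
}

#' Run one quantification pass over all samples
#'
#' Builds a fresh index over the pass's transcript set, quantifies every
#' sample independently, and assembles transcript- and gene-level TPM
#' matrices. There is no coupling across samples: each column equals a
#' standalone [quantifySample()] run.
#'
#' @param txSeqs named \code{DNAStringSet} of the pass's transcripts.
#' @param geneMap named character vector, transcript_id to gene_id,
#'   covering \code{txSeqs}.
#' @param reads named list; per sample a list with elements \code{r1},
#'   \code{r2} (\code{DNAStringSet}, character vectors, or FASTQ paths).
#' @param sampleInfo data.frame of sample metadata with a \code{sample}
#'   column matching \code{names(reads)} (tissue, animal, sex,
#'   library_type as available).
#' @param passNumber 1-based pass counter.
#' @param k,fragLenMean index parameters, see [buildIndex()].
#' @param stranded protocol flag, see [pseudoalign()].
#' @return a \linkS4class{PassResult}.
#' @export
runPass <- function(txSeqs, geneMap, reads, sampleInfo, passNumber = 1L,
                    k = 31L, fragLenMean = 200, stranded = TRUE) {
  if (!length(reads)) stop("at least one sample is required")
  if (!length(txSeqs)) stop("transcript set must be non-empty")
  sampleIds <- names(reads)
  if (is.null(sampleIds) || !all(sampleIds %in% sampleInfo$sample))
    stop("every sample must appear in sampleInfo$sample")
  index <- buildIndex(txSeqs, k = k, fragLenMean = fragLenMean)

  txn <- index@txNames
  genes <- unique(unname(geneMap[txn]))
  txTPM <- matrix(0, length(txn), length(sampleIds),
                  dimnames = list(txn, sampleIds))
  txCnt <- txTPM
  gTPM <- matrix(0, length(genes), length(sampleIds),
                 dimnames = list(genes, sampleIds))
  unassigned <- setNames(vector("list", length(sampleIds)), sampleIds)

  for (s in sampleIds) {
    r1 <- reads[[s]]$r1
    r2 <- reads[[s]]$r2
    if (length(r1) == 0L)
      warning("sample ", s, " has no reads; its column is all zero")
    q <- quantifySample(index, r1, r2, geneMap, stranded = stranded)
    txTPM[, s] <- q$abundance[txn, "tpm"]
    txCnt[, s] <- q$abundance[txn, "est_counts"]
    gTPM[match(q$genes$gene_id, genes), s] <- q$genes$tpm
    unassigned[[s]] <- q$unassigned$read_id
  }

  cd <- DataFrame(sampleInfo[match(sampleIds, sampleInfo$sample), ,
                             drop = FALSE], row.names = sampleIds)
  txSE <- SummarizedExperiment(
    assays = list(TPM = txTPM, est_counts = txCnt), colData = cd,
    rowData = DataFrame(gene_id = unname(geneMap[txn]), row.names = txn))
  gSE <- SummarizedExperiment(assays = list(TPM = gTPM), colData = cd)
  new("PassResult", passNumber = as.integer(passNumber),
      transcriptTPM = txSE, geneTPM = gSE, unassigned = unassigned,
      indexIds = txn)
}

#' Revise a transcript index between passes
#'
#' Removal: transcripts whose TPM is exactly 0 in every sample (when
#' \code{plan$dropAllZero}) and transcripts on the externally supplied
#' low-quality list. Addition: validated novel model identifiers. The
#' operation is idempotent: re-running on its own output with the same
#' plan changes nothing further.
#'
#' @param currentIds transcript identifiers of the current index.
#' @param expression transcript-level TPM matrix (or a
#'   SummarizedExperiment with a \code{TPM} assay) covering
#'   \code{currentIds}.
#' @param plan an [indexRevisionPlan()].
#' @return list with \code{ids} (the revised identifier set) and
#'   \code{log} (data.frame \code{transcript_id}, \code{action},
#'   \code{reason}; reasons are \code{all_zero},
#'   \code{low_quality_flag}, \code{novel_validated}, semicolon-joined
#'   when several apply).
#' @export
reviseIndex <- function(currentIds, expression, plan) {
  stopifnot(inherits(plan, "IndexRevisionPlan"))
  tpm <- if (is(expression, "SummarizedExperiment"))
    assay(expression, "TPM") else as.matrix(expression)
  if (!all(currentIds %in% rownames(tpm)))
    stop("expression must cover every current transcript")
  if (!all(plan$lowQualityIds %in% currentIds))
    stop("low-quality identifiers outside the current index: ",
         paste(head(setdiff(plan$lowQualityIds, currentIds), 5),
               collapse = ", "))
  collide <- intersect(plan$novelIds, currentIds)
  if (length(collide))
    stop("novel model identifier(s) collide with the current index: ",
         paste(head(collide, 5), collapse = ", "))

  zero <- if (plan$dropAllZero) {
    currentIds[rowSums(tpm[currentIds, , drop = FALSE] != 0) == 0L]
  } else character(0)
  removed <- union(zero, plan$lowQualityIds)
  reason <- vapply(removed, function(id)
    paste(c(if (id %in% zero) "all_zero",
            if (id %in% plan$lowQualityIds) "low_quality_flag"),
          collapse = ";"), character(1))
  log <- rbind(
    if (length(removed))
      data.frame(transcript_id = removed, action = "removed",
                 reason = unname(reason), stringsAsFactors = FALSE),
    if (length(plan$novelIds))
      data.frame(transcript_id = plan$novelIds, action = "added",
                 reason = "novel_validated", stringsAsFactors = FALSE))
  if (is.null(log))
    log <- data.frame(transcript_id = character(0), action = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  list(ids = c(setdiff(currentIds, removed), plan$novelIds), log = log)
}

#' Run the full multi-pass quantification pipeline
#'
#' Pass 1 quantifies all samples against the draft transcript set. The
#' index is then revised (all-zero transcripts and flagged low-quality
#' predictions removed) and pass 2 re-quantifies. Candidate novel models
#' are validated ([annotateNovelModels()]); the retained ones are
#' integrated into the index for pass 3, and quantification is repeated.
#' If validation rejects every candidate, pass 3 proceeds with a warning
#' on the pass-2 index.
#'
#' @param config list with elements: \code{genome} (named
#'   \code{DNAStringSet}), \code{models} (draft exon \code{GRanges}),
#'   \code{reads} (named per-sample list of \code{r1}/\code{r2}),
#'   \code{sampleInfo} (data.frame with a \code{sample} column), and
#'   optionally \code{candidateModels} (exon \code{GRanges}),
#'   \code{homology} (blast-tabular data.frame),
#'   \code{lowQualityIds} (character), \code{k} (default 31),
#'   \code{fragLenMean} (default 200), \code{stranded} (default TRUE),
#'   \code{dropAllZero} (default TRUE), \code{minPeptide} (default 50).
#' @return list with \code{passes} (list of \linkS4class{PassResult}),
#'   \code{revisions} (list of revision logs), \code{validation}
#'   (decisions data.frame or NULL), and \code{final} (the pass-3
#'   gene-level SummarizedExperiment).
#' @export
runMultipass <- function(config) {
  k <- config$k %||% 31L
  flm <- config$fragLenMean %||% 200
  stranded <- config$stranded %||% TRUE
  dropAllZero <- config$dropAllZero %||% TRUE
  lowQ <- config$lowQualityIds %||% character(0)

  draftSeqs <- transcriptSequences(config$genome, config$models)
  geneMap <- transcriptGeneMap(config$models)

  p1 <- runPass(draftSeqs, geneMap, config$reads, config$sampleInfo,
                passNumber = 1L, k = k, fragLenMean = flm,
                stranded = stranded)

  rev1 <- reviseIndex(p1@indexIds, transcriptTPM(p1),
                      indexRevisionPlan(dropAllZero = dropAllZero,
                                        lowQualityIds = lowQ,
                                        passNumber = 2L))
  p2 <- runPass(draftSeqs[rev1$ids], geneMap, config$reads,
                config$sampleInfo, passNumber = 2L, k = k,
                fragLenMean = flm, stranded = stranded)

  validation <- NULL
  novelIds <- character(0)
  novelSeqs <- DNAStringSet()
  if (!is.null(config$candidateModels) &&
      length(unique(mcols(config$candidateModels)$transcript_id))) {
    validation <- annotateNovelModels(
      config$genome, config$candidateModels,
      config$homology %||%
        data.frame(query_id = character(0), pident = numeric(0),
                   length = integer(0), gaps = integer(0),
                   evalue = numeric(0), sgenus = character(0),
                   sdescription = character(0), qlen = integer(0)),
      minPeptide = config$minPeptide %||% 50L)
    retained <- validation$retainedModels
    if (length(retained)) {
      novelSeqs <- transcriptSequences(config$genome, retained)
      novelIds <- names(novelSeqs)
      geneMap <- c(geneMap, transcriptGeneMap(retained))
    } else {
      warning("validation rejected all candidate models; ",
              "pass 3 keeps the pass-2 index")
    }
  }

  rev2 <- reviseIndex(rev1$ids, transcriptTPM(p2),
                      indexRevisionPlan(dropAllZero = FALSE,
                                        novelIds = novelIds,
                                        passNumber = 3L))
  p3 <- runPass(c(draftSeqs[intersect(rev2$ids, names(draftSeqs))],
                  novelSeqs),
                geneMap, config$reads, config$sampleInfo,
                passNumber = 3L, k = k, fragLenMean = flm,
                stranded = stranded)

  list(passes = list(p1, p2, p3),
       revisions = list(rev1$log, rev2$log),
       validation = if (is.null(validation)) NULL else validation$decisions,
       final = geneTPM(p3))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
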