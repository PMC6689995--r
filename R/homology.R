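#' Default genus whitelist for homology support
#'
#' The genera accepted as close-relative support for a novel
#' protein-coding model: Bison (bison), Bos (cow, yak), Camelus (camel),
#' Capra (goat), Ovis (sheep, mouflon), Pantholops (antelope) and Vicugna
#' (alpaca).
#'
#' @return character vector of genus names.
#' @export
ruminantGenera <- function() {
  c("Bison", "Bos", "Camelus", "Capra", "Ovis", "Pantholops", "Vicugna")
}

#' Default forbidden description keywords
#'
#' Alignments to subject proteins whose description contains any of these
#' (case-insensitive substring match) do not count as support: poorly
#' annotated or inferred entries. \code{"TPA:"} marks third-party
#' annotation.
#'
#' @return character vector of keywords.
#' @export
forbiddenDescriptionWords <- function() {
  c("low quality", "hypothetical", "unnamed", "uncharacterized",
    "putative", "TPA:")
}

#' Conservative homology-alignment filter for novel transcript models
#'
#' Parses blast-tabular alignments of candidate peptides. Rows above the
#' e-value threshold are dropped up front. A remaining alignment is valid
#' when it (a) has percent identity >= \code{minIdentity}, (b) covers at
#' least \code{minCoverage} of the query protein length, (c) is at least
#' \code{minAlignLength} amino acids long, (d) has no gaps, and (e) its
#' subject description contains none of the forbidden keywords. A query
#' is retained when it has at least \code{minAlignments} valid alignments
#' and at least one valid alignment is to a genus on the whitelist.
#'
#' @param alignments data.frame with at least columns \code{query_id},
#'   \code{pident}, \code{length}, \code{gaps}, \code{evalue},
#'   \code{sgenus}, \code{sdescription}, \code{qlen} (query protein
#'   length, amino acids).
#' @param genusWhitelist accepted genera (default [ruminantGenera()]).
#' @param minAlignments minimum number of valid alignments (default 5).
#' @param minIdentity minimum percent identity (default 90).
#' @param minCoverage minimum alignment length as a fraction of query
#'   length (default 0.9).
#' @param minAlignLength minimum alignment length in amino acids
#'   (default 50).
#' @param maxEvalue e-value pre-filter (default 1e-25).
#' @param forbiddenWords description exclusion keywords (default
#'   [forbiddenDescriptionWords()]).
#' @param queryIds optional identifiers to report on even when they have
#'   no alignment rows (reported as \code{too_few_alignments}).
#' @return data.frame with one row per query: \code{query_id},
#'   \code{retained}, \code{n_valid}, \code{has_whitelisted_genus},
#'   \code{failures} (semicolon-joined codes, empty when retained). The
#'   per-alignment evaluation is attached as attribute \code{"detail"}
#'   (columns \code{query_id}, \code{row}, \code{prefiltered},
#'   \code{valid}, \code{violated} as comma-joined codes).
#' @export
filterHomology <- function(alignments,
                           genusWhitelist = ruminantGenera(),
                           minAlignments = 5L,
                           minIdentity = 90,
                           minCoverage = 0.9,
                           minAlignLength = 50L,
                           maxEvalue = 1e-25,
                           forbiddenWords = forbiddenDescriptionWords(),
                           queryIds = NULL) {
  need <- c("query_id", "pident", "length", "gaps", "evalue", "sgenus",
            "sdescription", "qlen")
  if (!all(need %in% names(alignments)))
    stop("alignments must carry columns: ",
         paste(setdiff(need, names(alignments)), collapse = ", "))
  a <- alignments
  nr <- nrow(a)
  prefiltered <- if (nr) a$evalue <= maxEvalue else logical(0)
  descLower <- tolower(a$sdescription)
  hasForbidden <- Reduce(`|`, lapply(tolower(forbiddenWords), function(w)
    grepl(w, descLower, fixed = TRUE)), rep(FALSE, nr))
  fails <- list(
    identity = a$pident < minIdentity,
    coverage = a$length < minCoverage * a$qlen,
    min_length = a$length < minAlignLength,
    gaps = a$gaps > 0,
    forbidden_description = hasForbidden
  )
  violated <- apply(do.call(cbind, fails), 1L, function(v)
    paste(names(fails)[v], collapse = ","))
  if (!nr) violated <- character(0)
  valid <- prefiltered & !Reduce(`|`, fails, rep(FALSE, nr))

  detail <- data.frame(query_id = a$query_id, row = seq_len(nr),
                       prefiltered = prefiltered, valid = valid,
                       violated = violated, stringsAsFactors = FALSE)

  allQueries <- union(unique(a$query_id), queryIds)
  res <- lapply(allQueries, function(q) {
    idx <- which(a$query_id == q)
    v <- idx[valid[idx]]
    nValid <- length(v)
    hasGenus <- any(a$sgenus[v] %in% genusWhitelist)
    failures <- character(0)
    retained <- nValid >= minAlignments && hasGenus
    if (!retained) {
      if (nValid < minAlignments) {
        failures <- "too_few_alignments"
        bad <- idx[prefiltered[idx] & !valid[idx]]
        if (length(bad))
          failures <- c(failures, sort(unique(unlist(
            strsplit(violated[bad], ",", fixed = TRUE)))))
      } else {
        failures <- "no_ruminant_genus"
      }
    }
    data.frame(query_id = q, retained = retained, n_valid = nValid,
               has_whitelisted_genus = hasGenus,
               failures = paste(failures, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "detail") <- detail
  out
}

#' Decide which candidate novel transcript models are retained
#'
#' A candidate is retained as protein-coding only when its per-exon
#' longest-ORF chain passes all four structural criteria
#' ([validateOrfChain()]) and its peptide has conservative homology
#' support ([filterHomology()]). Candidates without any alignment record
#' proceed through the ORF stage but fail the homology stage.
#'
#' @param genome named \code{DNAStringSet}.
#' @param models exon-level \code{GRanges} of candidate models.
#' @param alignments blast-tabular data.frame keyed by transcript
#'   identifier in \code{query_id}.
#' @param minPeptide minimum concatenated peptide length (default 50 aa).
#' @param requireStartCodon passed to [longestOrfsPerExon()].
#' @param ... further arguments passed to [filterHomology()].
#' @return list with \code{retainedModels} (\code{GRanges} subset of
#'   \code{models}) and \code{decisions} (data.frame: one row per
#'   candidate with \code{transcript_id}, \code{retained},
#'   \code{orf_pass}, \code{homology_pass}, \code{orf_failures},
#'   \code{homology_failures}, \code{peptide_length}).
#' @export
annotateNovelModels <- function(genome, models, alignments,
                                minPeptide = 50L,
                                requireStartCodon = FALSE, ...) {
  txIds <- unique(mcols(models)$transcript_id)
  if (!length(txIds)) stop("no candidate models supplied")
  hom <- filterHomology(alignments, queryIds = txIds, ...)
  rows <- lapply(txIds, function(tx) {
    chain <- longestOrfsPerExon(genome, models, tx,
                                requireStartCodon = requireStartCodon)
    orf <- validateOrfChain(chain, minPeptide = minPeptide)
    h <- hom[hom$query_id == tx, ]
    data.frame(
      transcript_id = tx,
      retained = orf$pass && h$retained,
      orf_pass = orf$pass,
      homology_pass = h$retained,
      orf_failures = paste(orf$failures, collapse = ";"),
      homology_failures = h$failures,
      peptide_length = nchar(chainPeptide(chain)),
      stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  keep <- decisions$transcript_id[decisions$retained]
  list(retainedModels = models[mcols(models)$transcript_id %in% keep],
       decisions = decisions)
}
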