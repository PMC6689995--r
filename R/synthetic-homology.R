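#' Simulate a blast-like homology table with known pass/fail structure
#'
#' Emits blast-tabular records (outfmt-6 columns plus subject genus,
#' subject description and query length) engineered per query to either
#' satisfy every retention criterion or to violate exactly one named
#' criterion, together with ground-truth labels. Scenarios:
#' \describe{
#'   \item{all_pass}{5 valid alignments, at least one whitelisted genus
#'     (query retained).}
#'   \item{identity_fail}{one of 5 records has percent identity below 90,
#'     leaving 4 valid (rejected).}
#'   \item{coverage_fail}{one record covers less than 90\% of the query
#'     (rejected); needs query length >= 57 so the short alignment can
#'     still be >= 50 aa.}
#'   \item{length_fail}{one record is 49 aa long; isolating this
#'     criterion requires query length 50-54 so that 49 aa still covers
#'     90\% (rejected).}
#'   \item{gap_fail}{one record is gapped (rejected).}
#'   \item{description_fail}{one record's subject carries a forbidden
#'     description keyword (rejected).}
#'   \item{genus_fail}{5 valid records but none from a whitelisted genus
#'     (rejected).}
#'   \item{too_few}{only 3 records, all valid (rejected).}
#'   \item{evalue_fail}{one record has e-value above 1e-25 and is dropped
#'     by the pre-filter, leaving 4 (rejected).}
#' }
#'
#' @param queries data.frame with columns \code{query_id},
#'   \code{peptide_length} (amino acids, >= 1).
#' @param scenarios character vector of scenario names, recycled across
#'   queries (default \code{"all_pass"}).
#' @param seed integer seed.
#' @return list with \code{alignments} (data.frame: \code{query_id},
#'   \code{subject_id}, \code{pident}, \code{length}, \code{mismatch},
#'   \code{gaps}, \code{qstart}, \code{qend}, \code{sstart}, \code{send},
#'   \code{evalue}, \code{bitscore}, \code{sgenus}, \code{sdescription},
#'   \code{qlen}), \code{recordLabels} (per record: \code{query_id},
#'   \code{subject_id}, \code{valid}, \code{violated}) and
#'   \code{queryLabels} (per query: \code{query_id}, \code{scenario},
#'   \code{retain}).
#' @export
simulateHomologyTable <- function(queries, scenarios = "all_pass",
                                  seed = 1L) {
  stopifnot(all(c("query_id", "peptide_length") %in% names(queries)))
  if (any(queries$peptide_length < 1L))
    stop("peptide lengths must be >= 1")
  scenarios <- rep_len(scenarios, nrow(queries))
  known <- c("all_pass", "identity_fail", "coverage_fail", "length_fail",
             "gap_fail", "description_fail", "genus_fail", "too_few",
             "evalue_fail")
  if (!all(scenarios %in% known))
    stop("unknown scenario(s): ",
         paste(setdiff(scenarios, known), collapse = ", "))
  cleanDesc <- c("myosin heavy chain 7", "keratin, type II cytoskeletal 5",
                 "solute carrier family 16 member 1",
                 "peptidoglycan recognition protein 3",
                 "heat shock protein beta-1", "argonaute-2")
  badDesc <- c("hypothetical protein LOC102398", "unnamed protein product",
               "PREDICTED: uncharacterized protein C1orf100",
               "low quality protein: olfactory receptor",
               "putative serine protease", "TPA: zinc finger protein")
  offGenus <- c("Homo", "Mus", "Sus", "Equus", "Canis")

  aln <- list(); rec <- list(); qlab <- list()
  withSeed(seed, {
    for (i in seq_len(nrow(queries))) {
      q <- queries$query_id[i]
      L <- as.integer(queries$peptide_length[i])
      sc <- scenarios[i]
      nRec <- if (sc == "too_few") 3L else 5L
      if (sc %in% c("all_pass", "identity_fail", "gap_fail",
                    "description_fail", "genus_fail", "too_few",
                    "evalue_fail") && L < 56L)
        stop("scenario ", sc, " needs peptide_length >= 56 (query ", q, ")")
      if (sc == "coverage_fail" && L < 57L)
        stop("coverage_fail needs peptide_length >= 57 (query ", q, ")")
      if (sc == "length_fail" && (L < 50L || L > 54L))
        stop("length_fail needs peptide_length in 50..54 (query ", q, ")")

      lenLo <- max(50L, as.integer(ceiling(0.9 * L)))
      len <- sample(seq.int(lenLo, L), nRec, replace = TRUE)
      pid <- round(runif(nRec, 92, 99.5), 1)
      genus <- sample(ruminantGenera(), nRec, replace = TRUE)
      genus[1L] <- "Bos"
      desc <- sample(cleanDesc, nRec, replace = TRUE)
      gaps <- rep(0L, nRec)
      ev <- 10^runif(nRec, -80, -30)

      bad <- 3L  # the engineered violating record
      if (sc == "identity_fail") pid[bad] <- round(runif(1, 60, 89.4), 1)
      if (sc == "coverage_fail")
        len[bad] <- sample(seq.int(50L, as.integer(ceiling(0.9 * L)) - 1L), 1L)
      if (sc == "length_fail") len[bad] <- 49L
      if (sc == "gap_fail") gaps[bad] <- sample(1:5, 1L)
      if (sc == "description_fail") desc[bad] <- sample(badDesc, 1L)
      if (sc == "genus_fail") genus <- sample(offGenus, nRec, replace = TRUE)
      if (sc == "evalue_fail") ev[bad] <- 10^runif(1, -20, -5)

      tab <- data.frame(
        query_id = q,
        subject_id = sprintf("%s_subj%02d", q, seq_len(nRec)),
        pident = pid, length = len,
        mismatch = pmax(0L, as.integer(round(len * (100 - pid) / 100))),
        gaps = gaps, qstart = 1L, qend = pmin(len, L),
        sstart = 1L, send = len,
        evalue = ev, bitscore = round(runif(nRec, 150, 420), 1),
        sgenus = genus, sdescription = desc, qlen = L,
        stringsAsFactors = FALSE)

      ## label each record against the criteria (generator-side truth)
      viol <- character(nRec)
      for (j in seq_len(nRec)) {
        v <- character(0)
        if (tab$evalue[j] > 1e-25) v <- c(v, "evalue")
        if (tab$pident[j] < 90) v <- c(v, "identity")
        if (tab$length[j] < 0.9 * L) v <- c(v, "coverage")
        if (tab$length[j] < 50) v <- c(v, "min_length")
        if (tab$gaps[j] > 0) v <- c(v, "gaps")
        if (any(vapply(tolower(forbiddenDescriptionWords()), grepl,
                       logical(1), x = tolower(tab$sdescription[j]),
                       fixed = TRUE)))
          v <- c(v, "forbidden_description")
        viol[j] <- paste(v, collapse = ",")
      }
      isValid <- viol == ""
      retain <- sum(isValid) >= 5L &&
        any(tab$sgenus[isValid] %in% ruminantGenera())

      aln[[i]] <- tab
      rec[[i]] <- data.frame(query_id = q, subject_id = tab$subject_id,
                             valid = isValid, violated = viol,
                             stringsAsFactors = FALSE)
      qlab[[i]] <- data.frame(query_id = q, scenario = sc, retain = retain,
                              stringsAsFactors = FALSE)
    }
  })
  list(alignments = do.call(rbind, aln),
       recordLabels = do.call(rbind, rec),
       queryLabels = do.call(rbind, qlab))
}
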