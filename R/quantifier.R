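#' Build a k-mer index over a transcript set
#'
#' Stores the forward k-mers of every transcript at least k nucleotides
#' long. K-mers containing N are skipped. The index is strand-aware:
#' queries from the antisense mate are reverse-complemented at lookup
#' time rather than stored. Effective lengths are
#' \code{max(length - fragLenMean + 1, 1)}, the number of distinct
#' fragment start positions.
#'
#' @param transcripts named \code{DNAStringSet} (or named character
#'   vector) of transcript sequences over A, C, G, T, N.
#' @param k odd k-mer length, 11 to 31 (default 31).
#' @param fragLenMean assumed mean fragment length for effective lengths
#'   (default 200).
#' @return a \linkS4class{PseudoIndex}. Transcripts shorter than k are
#'   flagged unindexable with a warning.
#' @examples
#' idx <- buildIndex(c(t1 = paste(rep("ACGTT", 10), collapse = "")), k = 11)
#' idx
#' @export
buildIndex <- function(transcripts, k = 31L, fragLenMean = 200) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop("k must be odd and in [11, 31]")
  seqs <- setNames(as.character(transcripts), names(transcripts))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcripts must carry unique names")
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short))
    warning(sum(short), " transcript(s) shorter than k are unindexable: ",
            paste(head(names(seqs)[short], 5), collapse = ", "))
  idxable <- which(!short)
  nk <- lens[idxable] - k + 1L
  tx <- rep.int(idxable, nk)
  starts <- unlist(lapply(nk, seq_len), use.names = FALSE)
  kmer <- substring(seqs[tx], starts, starts + k - 1L)
  keep <- !grepl("N", kmer, fixed = TRUE)
  kt <- unique(data.table(kmer = kmer[keep], tx = tx[keep]))
  setkey(kt, kmer)
  new("PseudoIndex", k = k, kmerTable = kt, txNames = names(seqs),
      txLengths = setNames(as.integer(lens), names(seqs)),
      effLengths = setNames(pmax(lens - fragLenMean + 1, 1), names(seqs)),
      unindexable = names(seqs)[short], fragLenMean = fragLenMean)
}

## Compatibility sets for one query orientation: each pair's set is the
## intersection of the per-k-mer transcript sets over the pair's k-mers
## that occur in the index at all.
.pairCompat <- function(index, q1, q2, ids) {
  k <- index@k
  qs <- c(q1, q2)
  pairIdx <- rep(seq_along(ids), 2L)
  lens <- nchar(qs)
  nk <- pmax(lens - k + 1L, 0L)
  pr <- rep.int(pairIdx, nk)
  starts <- unlist(lapply(nk, seq_len), use.names = FALSE)
  kmer <- substring(qs[rep.int(seq_along(qs), nk)], starts, starts + k - 1L)
  qdt <- unique(data.table(pair = pr, kmer = kmer))
  hits <- index@kmerTable[qdt, on = "kmer", nomatch = NULL]
  if (!nrow(hits)) return(data.table(pair = integer(0), tx = integer(0)))
  nf <- hits[, .(nfound = uniqueN(kmer)), by = pair]
  cnt <- hits[, .N, by = .(pair, tx)]
  cnt <- nf[cnt, on = "pair"]
  cnt[N == nfound, .(pair, tx)]
}

#' Pseudoalign read pairs against a k-mer index
#'
#' Assigns each read pair to its transcript-compatibility equivalence
#' class: the intersection of the per-k-mer transcript sets over both
#' mates, ignoring k-mers absent from the index. Under the stranded
#' (dUTP) convention mate 1 is queried as-is and mate 2
#' reverse-complemented; with \code{stranded = FALSE} both pair
#' orientations are queried and their compatibility sets united. Pairs
#' with an empty final set are recorded as unassigned
#' (\code{no_compatible_transcript}), and pairs with a mate shorter than
#' k as unassigned with reason \code{read_shorter_than_k}.
#'
#' @param index a \linkS4class{PseudoIndex}.
#' @param r1,r2 named \code{DNAStringSet} (or named character vectors) of
#'   mates 1 and 2, in pair order.
#' @param stranded assume the stranded protocol (default TRUE).
#' @return an \linkS4class{EquivalenceClassCounts}.
#' @export
pseudoalign <- function(index, r1, r2, stranded = TRUE) {
  s1 <- setNames(as.character(r1), names(r1))
  s2 <- setNames(as.character(r2), names(r2))
  if (length(s1) != length(s2)) stop("r1 and r2 must pair up")
  ids <- names(s1)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_along(s1))
  k <- index@k

  tooShort <- nchar(s1) < k | nchar(s2) < k
  ok <- which(!tooShort)

  compat <- .pairCompat(index, s1[ok], revComp(s2[ok]), ids[ok])
  if (!stranded) {
    alt <- .pairCompat(index, revComp(s1[ok]), s2[ok], ids[ok])
    compat <- unique(rbind(compat, alt))
  }

  assignedLocal <- sort(unique(compat$pair))
  keys <- compat[, .(key = paste(sort(tx), collapse = ",")), by = pair]
  tab <- keys[, .N, by = key]
  classes <- lapply(strsplit(tab$key, ",", fixed = TRUE), as.integer)

  unassignedIdx <- ok[!seq_along(ok) %in% assignedLocal]
  unassigned <- c(ids[tooShort], ids[unassignedIdx])
  reasons <- c(rep("read_shorter_than_k", sum(tooShort)),
               rep("no_compatible_transcript", length(unassignedIdx)))

  new("EquivalenceClassCounts", classes = classes,
      counts = as.integer(tab$N), txNames = index@txNames,
      unassigned = unassigned, unassignedReason = reasons,
      nPairs = length(s1))
}

#' EM abundance estimation over equivalence classes
#'
#' Standard equivalence-class EM: the E-step fractionally assigns each
#' class count to its member transcripts proportional to
#' \code{alpha_t / effLen_t}; the M-step renormalizes \code{alpha} to the
#' expected counts. Iteration stops when the largest absolute change in
#' the \code{alpha} proportions falls below \code{tol} or after
#' \code{maxIter} iterations. TPM is
#' \code{(alpha_t/effLen_t) / sum_u(alpha_u/effLen_u) * 1e6}. The
#' equivalence-class log-likelihood in abundance space,
#' \code{sum_c n_c log(sum_(t in c) alpha_t/effLen_t)} with \code{alpha}
#' on the unit simplex, is recorded every iteration; this EM never
#' decreases it.
#'
#' @param ecs an \linkS4class{EquivalenceClassCounts}.
#' @param index the \linkS4class{PseudoIndex} the classes refer to.
#' @param tol convergence tolerance on the max absolute change of the
#'   alpha proportions (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return data.frame in abundance-table convention: \code{target_id},
#'   \code{length}, \code{eff_length}, \code{est_counts}, \code{tpm}
#'   (unindexable transcripts appear with zero counts and NA effective
#'   length). Attributes: \code{loglik} (per-iteration trace),
#'   \code{iterations}, \code{converged}.
#' @export
emAbundances <- function(ecs, index, tol = 1e-8, maxIter = 1000L) {
  stopifnot(tol > 0, maxIter >= 1L)
  txn <- index@txNames
  indexed <- setdiff(txn, index@unindexable)
  eff <- index@effLengths[indexed]

  out <- data.frame(target_id = txn,
                    length = as.numeric(index@txLengths[txn]),
                    eff_length = ifelse(txn %in% indexed,
                                        index@effLengths[txn], NA_real_),
                    est_counts = 0, tpm = 0, stringsAsFactors = FALSE)
  rownames(out) <- txn

  if (!length(ecs@classes) || sum(ecs@counts) == 0L) {
    warning("no assigned read pairs; returning an all-zero table")
    attr(out, "loglik") <- numeric(0)
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    return(out)
  }

  members <- unlist(ecs@classes, use.names = FALSE)      # tx index
  classOf <- rep.int(seq_along(ecs@classes), lengths(ecs@classes))
  n <- as.numeric(ecs@counts)
  total <- sum(n)
  pos <- match(txn[members], indexed)                    # into indexed set
  nt <- length(indexed)

  alpha <- rep(1 / nt, nt)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    dens <- alpha / eff
    w <- dens[pos]
    denom <- rowsum(w, classOf, reorder = TRUE)[, 1L]
    ll <- c(ll, sum(n * log(denom)))
    frac <- w / denom[classOf]
    cnt <- rowsum(frac * n[classOf], pos, reorder = FALSE)
    alphaNew <- rep(0, nt)
    alphaNew[as.integer(rownames(cnt))] <- cnt[, 1L] / total
    delta <- max(abs(alphaNew - alpha))
    alpha <- alphaNew
    if (delta < tol) { converged <- TRUE; break }
  }

  dens <- alpha / eff
  tpm <- dens / sum(dens) * 1e6
  out[indexed, "est_counts"] <- alpha * total
  out[indexed, "tpm"] <- tpm
  attr(out, "loglik") <- ll
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Summarize transcript abundances to the gene level
#'
#' Gene TPM (and estimated counts) are the sums over member transcripts,
#' so per-sample gene TPM still sums to one million.
#'
#' @param abundance abundance data.frame from [emAbundances()].
#' @param geneMap named character vector mapping transcript_id to
#'   gene_id.
#' @return data.frame with \code{gene_id}, \code{tpm}, \code{est_counts},
#'   ordered by first appearance of each gene in the abundance table.
#' @export
summarizeToGenes <- function(abundance, geneMap) {
  unmapped <- setdiff(abundance$target_id, names(geneMap))
  if (length(unmapped))
    stop("transcript(s) without a gene mapping: ",
         paste(head(unmapped, 10), collapse = ", "))
  g <- unname(geneMap[abundance$target_id])
  lev <- unique(g)
  tpm <- rowsum(abundance$tpm, factor(g, levels = lev), reorder = FALSE)
  cnt <- rowsum(abundance$est_counts, factor(g, levels = lev), reorder = FALSE)
  data.frame(gene_id = lev, tpm = tpm[, 1L], est_counts = cnt[, 1L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantify one sample end to end
#'
#' Convenience wrapper: pseudoalign a sample's read pairs, run the EM,
#' and summarize to genes.
#'
#' @param index a \linkS4class{PseudoIndex}.
#' @param r1,r2 mates (named \code{DNAStringSet}, named character
#'   vectors, or FASTQ file paths).
#' @param geneMap named character vector mapping transcript_id to
#'   gene_id.
#' @param stranded assume the stranded protocol (default TRUE).
#' @param tol,maxIter EM controls, see [emAbundances()].
#' @return list with \code{abundance} (transcript table), \code{genes}
#'   (gene table), \code{ec} (the \linkS4class{EquivalenceClassCounts}),
#'   and \code{unassigned} (data.frame of read ids and reasons).
#' @export
quantifySample <- function(index, r1, r2, geneMap, stranded = TRUE,
                           tol = 1e-8, maxIter = 1000L) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1))
    r1 <- readDNAStringSet(r1, format = "fastq")
  if (is.character(r2) && length(r2) == 1L && file.exists(r2))
    r2 <- readDNAStringSet(r2, format = "fastq")
  ec <- pseudoalign(index, r1, r2, stranded = stranded)
  ab <- emAbundances(ec, index, tol = tol, maxIter = maxIter)
  list(abundance = ab, genes = summarizeToGenes(ab, geneMap), ec = ec,
       unassigned = unassignedReads(ec))
}
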