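#' Simulate stranded paired-end reads from a transcript set
#'
#' Draws fragments from transcripts with probability proportional to
#' abundance times spliced length, uniform fragment start, and emits a
#' stranded pair per fragment: mate 1 is the 5' end of the fragment on
#' the transcript's sense strand, mate 2 the reverse complement of its 3'
#' end (dUTP-style protocol; the convention is recorded in the read
#' names). Sequencing error is i.i.d. substitution at \code{errorRate}
#' per base.
#'
#' Read names encode the originating transcript
#' (\code{read000001|rna0003|start}), which downstream tests use as
#' ground truth.
#'
#' @param txSeqs named \code{DNAStringSet} of transcript sense sequences.
#' @param abundances named numeric vector (e.g. TPM) covering every
#'   transcript in \code{txSeqs}.
#' @param nPairs number of read pairs (> 0).
#' @param readLen read length (default 100); must not exceed the length
#'   of any transcript with positive abundance.
#' @param errorRate per-base substitution probability (default 0).
#' @param fragLen target fragment length (default 200), truncated to the
#'   transcript length.
#' @param seed integer seed.
#' @return list with \code{r1}, \code{r2} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame \code{read_id}, \code{transcript_id},
#'   \code{start}).
#' @export
simulateReads <- function(txSeqs, abundances, nPairs, readLen = 100L,
                          errorRate = 0, fragLen = 200L, seed = 1L) {
  if (nPairs < 1L) stop("nPairs must be > 0")
  if (!all(names(txSeqs) %in% names(abundances)))
    stop("abundances must cover all transcripts")
  ab <- abundances[names(txSeqs)]
  if (all(ab == 0)) stop("all abundances are zero")
  lens <- width(txSeqs)
  wts <- ab * lens
  usable <- wts > 0
  if (any(lens[usable] < readLen))
    stop("readLen exceeds the length of transcript(s) with positive ",
         "abundance: ",
         paste(head(names(txSeqs)[usable & lens < readLen], 5), collapse = ", "))
  seqsChr <- as.character(txSeqs)

  withSeed(seed, {
    pick <- sample.int(length(txSeqs), nPairs, replace = TRUE,
                       prob = wts / sum(wts))
    fl <- pmin(fragLen, lens[pick])
    fl <- pmax(fl, readLen)
    startMax <- lens[pick] - fl + 1L
    st <- 1L + floor(runif(nPairs) * startMax)
    frag <- substring(seqsChr[pick], st, st + fl - 1L)
    m1 <- substring(frag, 1L, readLen)
    m2 <- revComp(substring(frag, nchar(frag) - readLen + 1L, nchar(frag)))
    if (errorRate > 0) {
      m1 <- .addSubstitutions(m1, errorRate)
      m2 <- .addSubstitutions(m2, errorRate)
    }
    ids <- sprintf("read%06d|%s|%d|mate1_sense", seq_len(nPairs),
                   names(txSeqs)[pick], st)
    truth <- data.frame(read_id = ids,
                        transcript_id = names(txSeqs)[pick],
                        start = st, stringsAsFactors = FALSE)
    list(r1 = DNAStringSet(setNames(m1, ids)),
         r2 = DNAStringSet(setNames(m2, ids)),
         truth = truth)
  })
}

## Random substitutions at a fixed per-base rate. The substituted base is
## drawn from the three alternatives.
.addSubstitutions <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(reads[1L])
  for (i in seq_along(reads)) {
    hit <- which(runif(n) < rate)
    if (!length(hit)) next
    s <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    reads[i] <- paste(s, collapse = "")
  }
  reads
}
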