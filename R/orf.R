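## Per-exon longest-ORF engine. An ORF here is a maximal stop-codon-free
## stretch of whole codons in one reading frame ("stop-to-stop"); no start
## codon is required by default, because internal exons of a genuine CDS
## need not begin with ATG. Stops are TAA/TAG/TGA (standard code only).

## Longest stop-free run within one frame's codon vector. Returns codon
## coordinates; ties go to the 5'-most run. With requireStartCodon, a run
## only counts from its first ATG.
.frameBestRun <- function(codons, requireStartCodon = FALSE) {
  n <- length(codons)
  if (!n) return(list(len = 0L, startCodon = NA_integer_, stop = FALSE))
  isStop <- codons %in% STOP_CODONS
  runs <- rle(isStop)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- list(len = 0L, startCodon = NA_integer_, stop = FALSE)
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) next
    s <- starts[i]
    if (requireStartCodon) {
      atg <- which(codons[s:ends[i]] == "ATG")
      if (!length(atg)) next
      s <- s + atg[1L] - 1L
    }
    len <- ends[i] - s + 1L
    stop <- ends[i] < n
    if (len + as.integer(stop) > best$len + as.integer(best$stop)) {
      best <- list(len = len, startCodon = s, stop = stop)
    }
  }
  best
}

## Best ORF in each of the six frames of a genomic sequence. Positions
## are within the scanned string in its reading direction (the reverse
## complement for minus-strand frames). `extent` is the span used to
## rank ORFs as "longest": the stop-free run plus its terminating stop
## codon when one is present, so a stop-terminated reading stretch is
## not out-ranked by an open run it fully matches in coding length.
.allFrameOrfs <- function(genomicSeq, requireStartCodon = FALSE) {
  out <- vector("list", 6L)
  i <- 0L
  for (st in c("+", "-")) {
    s <- if (st == "+") genomicSeq else revComp(genomicSeq)
    for (frame in 0:2) {
      run <- .frameBestRun(frameCodons(s, frame), requireStartCodon)
      i <- i + 1L
      orf_start <- if (run$len > 0L) frame + 3L * (run$startCodon - 1L) + 1L else NA_integer_
      out[[i]] <- data.frame(
        strand = st, frame = frame,
        orf_start = orf_start,
        orf_end = if (run$len > 0L) orf_start + 3L * run$len - 1L else NA_integer_,
        orf_nt = 3L * run$len,
        has_terminal_stop = run$stop,
        extent = 3L * (run$len + as.integer(run$stop && run$len > 0L)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-exon longest ORFs of a candidate transcript model
#'
#' For each exon of the transcript, independently scans all six reading
#' frames (three per strand) of the exon's genomic sequence for the
#' longest stop-codon-free stretch of whole codons, recording its strand,
#' span, and whether it is terminated by an in-frame stop codon (as
#' opposed to simply running off the exon end). The translated ORFs are
#' concatenated into a candidate peptide in transcript 5'-to-3' exon
#' order. Exons shorter than one codon yield an empty ORF.
#'
#' "Longest" ranks candidate ORFs by their stop-inclusive extent: a
#' reading stretch terminated by a stop codon spans the stop as well, so
#' it is not out-ranked by an open run of equal coding length in another
#' frame. The reported \code{orf_nt} and the translated peptide exclude
#' the stop. Remaining ties break deterministically: plus strand before
#' minus, lower frame first, 5'-most run first.
#'
#' @param genome named \code{DNAStringSet}.
#' @param models exon-level \code{GRanges}.
#' @param transcriptId the transcript to decompose.
#' @param requireStartCodon if TRUE, ORFs only count from their first ATG.
#' @return an \linkS4class{OrfChain}.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = "ATGGCCGCCTAAGG"))
#' mod <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12), "+")
#' S4Vectors::mcols(mod) <- S4Vectors::DataFrame(
#'   transcript_id = "rna0001", gene_id = "gene0001", exon_number = 1L,
#'   exon_id = "exon000001", biotype = "protein_coding")
#' chainPeptide(longestOrfsPerExon(gen, mod, "rna0001"))  # "MAA"
#' @export
longestOrfsPerExon <- function(genome, models, transcriptId,
                               requireStartCodon = FALSE) {
  ex <- models[mcols(models)$transcript_id == transcriptId]
  if (!length(ex)) stop("unknown transcript: ", transcriptId)
  ex <- ex[order(mcols(ex)$exon_number)]
  chroms <- as.character(seqnames(ex))
  if (!all(chroms %in% names(genome)))
    stop("exon chromosome(s) missing from genome: ",
         paste(setdiff(chroms, names(genome)), collapse = ", "))
  if (any(end(ex) > width(genome)[match(chroms, names(genome))]) ||
      any(start(ex) < 1L))
    stop("exon coordinates outside chromosome for transcript ", transcriptId)

  rows <- vector("list", length(ex))
  pept <- character(length(ex))
  for (r in seq_along(ex)) {
    gseq <- substring(as.character(genome[[chroms[r]]]), start(ex)[r], end(ex)[r])
    w <- nchar(gseq)
    if (w < 3L) {
      rows[[r]] <- data.frame(
        exon_rank = r, exon_nt = w, orf_strand = NA_character_,
        orf_start = NA_integer_, orf_end = NA_integer_, orf_nt = 0L,
        has_terminal_stop = FALSE, stringsAsFactors = FALSE)
      pept[r] <- ""
      next
    }
    cand <- .allFrameOrfs(gseq, requireStartCodon)
    best <- cand[which.max(cand$extent), ]
    if (best$orf_nt == 0L) {
      rows[[r]] <- data.frame(
        exon_rank = r, exon_nt = w, orf_strand = NA_character_,
        orf_start = NA_integer_, orf_end = NA_integer_, orf_nt = 0L,
        has_terminal_stop = FALSE, stringsAsFactors = FALSE)
      pept[r] <- ""
      next
    }
    rows[[r]] <- data.frame(
      exon_rank = r, exon_nt = w, orf_strand = best$strand,
      orf_start = best$orf_start, orf_end = best$orf_end,
      orf_nt = best$orf_nt, has_terminal_stop = best$has_terminal_stop,
      stringsAsFactors = FALSE)
    scanned <- if (best$strand == "+") gseq else revComp(gseq)
    orfSeq <- substring(scanned, best$orf_start, best$orf_end)
    pept[r] <- as.character(translate(DNAStringSet(orfSeq))[[1L]])
  }
  new("OrfChain", transcriptId = transcriptId,
      exons = do.call(rbind, rows), peptide = paste(pept, collapse = ""))
}

#' Apply the protein-coding retention criteria to an ORF chain
#'
#' The four criteria, applied exactly and all reported when violated:
#' (a) the longest ORF of every exon lies on the same strand;
#' (b) the last ORF (3'-most exon) terminates in a stop codon, rather
#' than simply remaining open to the exon end; (c) no internal exon's ORF
#' is terminated by a stop codon before the exon end (the ORF need not
#' span the whole exon, but must end when the exon does); and (d) the
#' concatenated peptide is at least \code{minPeptide} amino acids.
#'
#' @param chain an \linkS4class{OrfChain}.
#' @param minPeptide minimum peptide length in amino acids (default 50).
#' @return list with \code{pass} (logical) and \code{failures} (character
#'   subset of \code{a_strand}, \code{b_terminal_stop},
#'   \code{c_internal_stop}, \code{d_min_length}).
#' @export
validateOrfChain <- function(chain, minPeptide = 50L) {
  stopifnot(is(chain, "OrfChain"))
  ex <- chain@exons
  if (!nrow(ex)) stop("empty ORF chain")
  failures <- character(0)
  strands <- ex$orf_strand[ex$orf_nt > 0L]
  if (length(unique(strands)) > 1L) failures <- c(failures, "a_strand")
  last <- ex[nrow(ex), ]
  if (!(last$orf_nt > 0L && last$has_terminal_stop))
    failures <- c(failures, "b_terminal_stop")
  if (nrow(ex) > 1L && any(ex$has_terminal_stop[-nrow(ex)]))
    failures <- c(failures, "c_internal_stop")
  if (nchar(chain@peptide) < minPeptide)
    failures <- c(failures, "d_min_length")
  list(pass = length(failures) == 0L, failures = failures)
}
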