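#' Generate a toy genome and multi-exon transcript models
#'
#' Lays one locus per gene along a small set of random chromosomes
#' (25 genes per chromosome, 100-nt spacers), alternating strands so both
#' are always represented. Each gene gets 2-4 exons of 150-300 nt
#' separated by 80-200 nt introns; when the design asks for multiple
#' transcripts per gene, additional isoforms skip one internal exon
#' (genes with only two exons repeat the full structure under a new
#' transcript identifier). Placeholder identifiers follow the
#' \code{geneX / rnaY / exonZ} convention with zero-padded numeric
#' suffixes. Deterministic for a fixed design seed.
#'
#' @param design a \linkS4class{SyntheticDesign}.
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{models} (\code{GRanges} of exon rows with metadata columns
#'   \code{transcript_id}, \code{gene_id}, \code{exon_number},
#'   \code{exon_id}, \code{biotype}).
#' @examples
#' d <- syntheticDesign(nGenes = 12, nTissues = 4, seed = 3,
#'                      modules = defaultModules(2, 4))
#' gm <- generateGenomeAndModels(d)
#' gm$models[1:4]
#' @export
generateGenomeAndModels <- function(design) {
  stopifnot(is(design, "SyntheticDesign"))
  if (design@nGenes < 1L) stop("design must contain at least one gene")
  roles <- geneRoles(design)
  n <- design@nGenes
  nPerChrom <- 25L
  withSeed(design@seed, {
    chromOf <- paste0("chr", sprintf("%02d", ((seq_len(n) - 1L) %/% nPerChrom) + 1L))
    strandOf <- rep(c("+", "-"), length.out = n)
    offsets <- setNames(rep(0L, length(unique(chromOf))), unique(chromOf))

    rows <- vector("list", n)
    txCounter <- 0L
    exonCounter <- 0L
    for (g in seq_len(n)) {
      nEx <- sample(2:4, 1L)
      exLens <- sample(150:300, nEx, replace = TRUE)
      intLens <- if (nEx > 1L) sample(80:200, nEx - 1L, replace = TRUE) else integer(0)
      chrom <- chromOf[g]
      gStart <- offsets[[chrom]] + 101L
      exStarts <- integer(nEx)
      pos <- gStart
      for (e in seq_len(nEx)) {
        exStarts[e] <- pos
        pos <- pos + exLens[e] + if (e < nEx) intLens[e] else 0L
      }
      exEnds <- exStarts + exLens - 1L
      offsets[[chrom]] <- exEnds[nEx]

      ## exon usage per transcript: isoform 1 keeps all exons, later
      ## isoforms skip one internal exon in rotation
      txRows <- list()
      for (j in seq_len(design@transcriptsPerGene)) {
        keep <- seq_len(nEx)
        if (j > 1L && nEx > 2L) {
          skip <- 2L + ((j - 2L) %% (nEx - 2L))
          keep <- setdiff(keep, skip)
        }
        txCounter <- txCounter + 1L
        txId <- padId("rna", txCounter)
        ranks <- if (strandOf[g] == "+") seq_along(keep) else rev(seq_along(keep))
        exonCounter <- exonCounter + length(keep)
        txRows[[j]] <- data.frame(
          chrom = chrom, start = exStarts[keep], end = exEnds[keep],
          strand = strandOf[g], transcript_id = txId,
          gene_id = roles$gene_id[g], exon_number = ranks,
          exon_id = padId("exon", exonCounter - length(keep) + seq_along(keep), 6L),
          biotype = roles$biotype[g], stringsAsFactors = FALSE)
      }
      rows[[g]] <- do.call(rbind, txRows)
    }
    tab <- do.call(rbind, rows)

    chromLens <- vapply(unique(chromOf), function(ch)
      offsets[[ch]] + 100L, integer(1))
    genome <- DNAStringSet(vapply(chromLens, randomDNA, character(1)))
    names(genome) <- names(chromLens)

    models <- GRanges(tab$chrom, IRanges(tab$start, tab$end),
                      strand = tab$strand)
    mcols(models) <- DataFrame(tab[, c("transcript_id", "gene_id",
                                       "exon_number", "exon_id", "biotype")])
    list(genome = genome, models = models)
  })
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements the result for minus-strand models, yielding the
#' transcript's sense sequence.
#'
#' @param genome named \code{DNAStringSet} of chromosomes.
#' @param models exon-level \code{GRanges} as produced by
#'   [generateGenomeAndModels()].
#' @return named \code{DNAStringSet}, one entry per transcript, in order
#'   of first appearance in \code{models}.
#' @export
transcriptSequences <- function(genome, models) {
  txIds <- unique(mcols(models)$transcript_id)
  out <- vapply(txIds, function(tx) {
    ex <- models[mcols(models)$transcript_id == tx]
    if (any(end(ex) > width(genome)[match(as.character(seqnames(ex)), names(genome))]))
      stop("exon coordinates outside chromosome for transcript ", tx)
    ex <- ex[order(start(ex))]
    chrom <- as.character(seqnames(ex))[1]
    pieces <- substring(as.character(genome[[chrom]]), start(ex), end(ex))
    s <- paste(pieces, collapse = "")
    if (as.character(strand(ex))[1] == "-") s <- revComp(s)
    s
  }, character(1))
  DNAStringSet(setNames(out, txIds))
}

#' Transcript-to-gene map of a model set
#'
#' @param models exon-level \code{GRanges}.
#' @return named character vector mapping transcript_id to gene_id.
#' @export
transcriptGeneMap <- function(models) {
  md <- unique(data.frame(tx = mcols(models)$transcript_id,
                          gene = mcols(models)$gene_id,
                          stringsAsFactors = FALSE))
  setNames(md$gene, md$tx)
}

#' Rewrite transcript loci with protein-coding sequence
#'
#' Replaces the exonic genome sequence of the given transcripts with
#' engineered coding content: every exon carries a stop-free reading frame
#' on the transcript's sense strand spanning all complete codons, and the
#' 3'-most exon ends that frame with a TAA stop codon. Candidate exon
#' sequences are resampled until the engineered ORF is strictly the
#' longest open reading frame across all six frames of the exon, so the
#' resulting models satisfy the per-exon longest-ORF retention criteria by
#' construction. Used to plant validated novel transcript models in
#' synthetic multi-pass runs.
#'
#' @param genome named \code{DNAStringSet}.
#' @param models exon-level \code{GRanges}.
#' @param txIds transcripts to rewrite.
#' @param seed integer seed.
#' @return modified copy of \code{genome}.
#' @export
plantCodingSequences <- function(genome, models, txIds, seed = 1L) {
  nonStop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")), 1, paste,
                           collapse = ""), STOP_CODONS)
  gchars <- as.list(setNames(as.character(genome), names(genome)))
  withSeed(seed, {
    for (tx in txIds) {
      ex <- models[mcols(models)$transcript_id == tx]
      if (!length(ex)) stop("unknown transcript: ", tx)
      ex <- ex[order(mcols(ex)$exon_number)]
      st <- as.character(strand(ex))[1]
      for (r in seq_along(ex)) {
        w <- width(ex)[r]
        nCod <- w %/% 3L
        rem <- w %% 3L
        if (nCod < 2L) stop("exon too short to carry coding sequence")
        isLast <- r == length(ex)
        repeat {
          codons <- sample(nonStop, nCod, replace = TRUE)
          if (isLast) codons[nCod] <- "TAA"
          sense <- paste0(paste(codons, collapse = ""),
                          if (rem > 0) randomDNA(rem) else "")
          intendedNt <- 3L * (nCod - as.integer(isLast))
          best <- .allFrameOrfs(if (st == "+") sense else revComp(sense))
          top <- best[which.max(best$extent), ]
          ok <- top$orf_nt == intendedNt &&
            top$strand == st &&
            sum(best$extent == top$extent) == 1L &&
            top$has_terminal_stop == isLast
          if (ok) break
        }
        chrom <- as.character(seqnames(ex))[r]
        genomic <- if (st == "+") sense else revComp(sense)
        s <- gchars[[chrom]]
        substr(s, start(ex)[r], end(ex)[r]) <- genomic
        gchars[[chrom]] <- s
      }
    }
  })
  DNAStringSet(unlist(gchars))
}
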