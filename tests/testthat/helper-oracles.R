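## Independent oracle implementations used across test files. These are
## deliberately naive re-implementations kept separate from the package's
## code paths.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(SummarizedExperiment)
})

smallDesign <- function(seed = 1L, ...) {
  syntheticDesign(nGenes = 40L, nTissues = 6L, replicates = 2L,
                  modules = defaultModules(3L, 8L), seed = seed, ...)
}

## Brute-force longest-ORF oracle: enumerate every maximal stop-free
## codon stretch in all six frames and return the max stop-inclusive
## extent in nt (a stretch terminated by a stop codon spans the stop).
oracleLongestOrfExtent <- function(seq) {
  rc <- as.character(reverseComplement(DNAString(seq)))
  best <- 0L
  for (s in c(seq, rc)) {
    for (frame in 0:2) {
      n <- nchar(s)
      if (n - frame < 3) next
      starts <- seq.int(1 + frame, n - 2, by = 3)
      codons <- substring(s, starts, starts + 2)
      isStop <- codons %in% c("TAA", "TAG", "TGA")
      run <- 0L
      for (i in seq_along(codons)) {
        if (isStop[i]) {
          extent <- run + 1L    # the stop codon belongs to the stretch
          if (extent > best) best <- extent
          run <- 0L
        } else {
          run <- run + 1L
          if (run > best) best <- run
        }
      }
    }
  }
  3L * best
}

## Independent homology filter: plain per-query loop, coded from the
## criteria list.
oracleHomologyFilter <- function(aln, minAln = 5, minIdent = 90,
                                 minCov = 0.9, minLen = 50,
                                 whitelist = c("Bison", "Bos", "Camelus",
                                               "Capra", "Ovis",
                                               "Pantholops", "Vicugna"),
                                 evMax = 1e-25) {
  bad <- c("low quality", "hypothetical", "unnamed", "uncharacterized",
           "putative", "tpa:")
  out <- list()
  for (q in unique(aln$query_id)) {
    rows <- aln[aln$query_id == q, ]
    nValid <- 0L
    genusOK <- FALSE
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$evalue > evMax) next
      if (r$pident < minIdent) next
      if (r$length < minCov * r$qlen) next
      if (r$length < minLen) next
      if (r$gaps > 0) next
      d <- tolower(r$sdescription)
      if (any(vapply(bad, function(w) grepl(w, d, fixed = TRUE),
                     logical(1)))) next
      nValid <- nValid + 1L
      if (r$sgenus %in% whitelist) genusOK <- TRUE
    }
    out[[q]] <- nValid >= minAln && genusOK
  }
  unlist(out)
}

## Exact-substring-search pseudoalignment oracle: a pair is compatible
## with every transcript containing mate 1 and the reverse complement of
## mate 2 as forward substrings.
oracleECCounts <- function(txSeqs, r1, r2) {
  h1 <- vwhichPDict(PDict(r1), txSeqs)
  h2 <- vwhichPDict(PDict(reverseComplement(r2)), txSeqs)
  n <- length(r1)
  compat <- vector("list", n)
  for (t in seq_along(txSeqs)) {
    both <- intersect(h1[[t]], h2[[t]])
    for (p in both) compat[[p]] <- c(compat[[p]], t)
  }
  keys <- vapply(compat, function(tx) {
    if (is.null(tx)) "" else paste(sort(names(txSeqs)[tx]), collapse = ",")
  }, character(1))
  counts <- table(keys[keys != ""])
  list(classes = setNames(as.integer(counts), names(counts)),
       unassigned = names(r1)[keys == ""])
}

## Direct numerical maximization of the equivalence-class likelihood
## sum_c n_c log(sum_(t in c) alpha_t / eff_t) over the abundance
## simplex (softmax parameterization, multi-start BFGS). Returns the
## read-origin probabilities mu = (alpha/eff) / sum(alpha/eff) for
## comparison with TPM/1e6.
oracleEMOptimum <- function(classes, counts, eff) {
  nTx <- length(eff)
  nll <- function(theta) {
    a <- exp(c(theta, 0))
    a <- a / sum(a)
    b <- a / eff
    -sum(counts * log(vapply(classes, function(m) sum(b[m]), numeric(1))))
  }
  best <- NULL
  for (s in 1:5) {
    set.seed(s)
    fit <- optim(rnorm(nTx - 1), nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a <- exp(c(best$par, 0))
  a <- a / sum(a)
  (a / eff) / sum(a / eff)
}

## Pearson correlation from the covariance/sd definition.
oracleCor <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sd(x) * sd(y))
}

## A random equivalence-class configuration for EM property tests.
randomECConfig <- function(seed) {
  set.seed(seed)
  nTx <- sample(3:8, 1)
  txn <- paste0("t", seq_len(nTx))
  nClass <- sample(2:10, 1)
  classes <- unique(lapply(seq_len(nClass), function(i)
    sort(sample(nTx, sample(1:min(3, nTx), 1)))))
  counts <- sample(1:500, length(classes), replace = TRUE)
  idx <- new("PseudoIndex", k = 31L,
             kmerTable = data.table::data.table(kmer = character(0),
                                                tx = integer(0)),
             txNames = txn,
             txLengths = setNames(sample(200:2000, nTx), txn),
             effLengths = setNames(runif(nTx, 50, 1500), txn),
             unindexable = character(0), fragLenMean = 200)
  ec <- new("EquivalenceClassCounts", classes = classes,
            counts = as.integer(counts), txNames = txn,
            unassigned = character(0), unassignedReason = character(0),
            nPairs = as.integer(sum(counts)))
  list(index = idx, ec = ec)
}

## Construct an OrfChain directly from a per-exon description table
## (used for table-driven rule tests).
makeChain <- function(strands, terminal, peptideLen, txId = "rnaX") {
  n <- length(strands)
  perExon <- pmax(1L, c(rep(peptideLen %/% n, n - 1),
                        peptideLen - (n - 1) * (peptideLen %/% n)))
  new("OrfChain", transcriptId = txId,
      exons = data.frame(
        exon_rank = seq_len(n), exon_nt = 3L * perExon + 2L,
        orf_strand = strands, orf_start = 1L,
        orf_end = 3L * perExon, orf_nt = 3L * perExon,
        has_terminal_stop = terminal, stringsAsFactors = FALSE),
      peptide = paste(rep("A", sum(perExon)), collapse = ""))
}

## Single-exon transcript model on a one-chromosome genome.
mkSingleExonModel <- function(seq, strand = "+", tx = "rna0001") {
  genome <- Biostrings::DNAStringSet(setNames(seq, "chr1"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, nchar(seq)),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcript_id = tx, gene_id = "gene0001", exon_number = 1L,
    exon_id = "exon000001", biotype = "protein_coding")
  list(genome = genome, models = gr)
}

## Random homology table straddling every threshold, plus query ids.
randomHomologyTable <- function(nRows, nQueries, seed) {
  set.seed(seed)
  q <- paste0("q", sample(nQueries, nRows, replace = TRUE))
  qlen <- setNames(sample(50:120, nQueries, replace = TRUE),
                   paste0("q", seq_len(nQueries)))
  desc <- sample(c("myosin heavy chain", "hypothetical protein",
                   "keratin 5", "unnamed protein product",
                   "putative kinase", "solute carrier 16A1",
                   "TPA: zinc finger", "collagen alpha-1"),
                 nRows, replace = TRUE)
  data.frame(
    query_id = q,
    subject_id = paste0("s", seq_len(nRows)),
    pident = round(runif(nRows, 80, 100), 1),
    length = sample(40:120, nRows, replace = TRUE),
    mismatch = 0L,
    gaps = sample(0:1, nRows, replace = TRUE, prob = c(0.8, 0.2)),
    qstart = 1L, qend = 1L, sstart = 1L, send = 1L,
    evalue = 10^runif(nRows, -60, -10),
    bitscore = 200,
    sgenus = sample(c("Bos", "Ovis", "Capra", "Homo", "Mus"),
                    nRows, replace = TRUE),
    sdescription = desc,
    qlen = unname(qlen[q]),
    stringsAsFactors = FALSE)
}
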