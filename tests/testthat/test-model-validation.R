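test_that("longest ORF per exon matches hand-translatable cases", {
  ## "ATGGCCGCCTAA": longest ORF translates MAA with a terminal stop
  m <- mkSingleExonModel("ATGGCCGCCTAA")
  ch <- longestOrfsPerExon(m$genome, m$models, "rna0001")
  expect_identical(chainPeptide(ch), "MAA")
  tab <- orfTable(ch)
  expect_equal(tab$orf_nt, 9L)
  expect_true(tab$has_terminal_stop)

  ## all-A exon: ORF spans every complete codon, never hits a stop
  m2 <- mkSingleExonModel(paste(rep("A", 60), collapse = ""))
  ch2 <- longestOrfsPerExon(m2$genome, m2$models, "rna0001")
  tab2 <- orfTable(ch2)
  expect_equal(tab2$orf_nt, 60L)
  expect_false(tab2$has_terminal_stop)

  ## coordinates outside the chromosome are rejected
  m3 <- mkSingleExonModel("ATGGCCTAA")
  GenomicRanges::end(m3$models) <- 50L
  expect_error(longestOrfsPerExon(m3$genome, m3$models, "rna0001"),
               "outside")
})

test_that("longest-ORF lengths equal exhaustive six-frame enumeration", {
  set.seed(17)
  for (i in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1)
    m <- mkSingleExonModel(seq, strand = strand)
    ch <- longestOrfsPerExon(m$genome, m$models, "rna0001")
    tab <- orfTable(ch)
    expect_equal(tab$orf_nt + 3L * tab$has_terminal_stop,
                 oracleLongestOrfExtent(seq), info = paste("exon", i))
  }
})

test_that("ORF-chain criteria are applied exactly and report all failures", {
  ## pass: both ORFs '+', last terminal stop, no internal stop, 60 aa
  ok <- makeChain(c("+", "+"), c(FALSE, TRUE), 60L)
  res <- validateOrfChain(ok)
  expect_true(res$pass)
  expect_length(res$failures, 0L)

  ## boundary: 49 aa < 50 fails d only
  short <- makeChain(c("+", "+"), c(FALSE, TRUE), 49L)
  expect_identical(validateOrfChain(short)$failures, "d_min_length")

  ## mixed strands fail a
  mixed <- makeChain(c("+", "-"), c(FALSE, TRUE), 60L)
  expect_identical(validateOrfChain(mixed)$failures, "a_strand")

  ## internal stop fails c; missing terminal stop fails b
  internal <- makeChain(c("+", "+", "+"), c(TRUE, FALSE, TRUE), 60L)
  expect_identical(validateOrfChain(internal)$failures, "c_internal_stop")
  open <- makeChain(c("+", "+"), c(FALSE, FALSE), 60L)
  expect_identical(validateOrfChain(open)$failures, "b_terminal_stop")

  ## several violations are all listed
  multi <- makeChain(c("+", "-"), c(TRUE, FALSE), 30L)
  expect_setequal(validateOrfChain(multi)$failures,
                  c("a_strand", "b_terminal_stop", "c_internal_stop",
                    "d_min_length"))

  ## table-driven dual reading of the rule set on random chains
  set.seed(23)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    terminal <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pep <- sample(30:80, 1)
    chain <- makeChain(strands, terminal, pep)
    res <- validateOrfChain(chain)
    ## independent re-reading of the criteria
    expFail <- c(
      if (length(unique(strands)) > 1) "a_strand",
      if (!terminal[n]) "b_terminal_stop",
      if (n > 1 && any(terminal[-n])) "c_internal_stop",
      if (pep < 50) "d_min_length")
    if (is.null(expFail)) expFail <- character(0)
    expect_setequal(res$failures, expFail)
    expect_equal(res$pass, length(expFail) == 0)
  }
})

test_that("homology filter matches the criteria list and brute force", {
  ## the canonical retained case: 5 clean ruminant alignments
  ht <- simulateHomologyTable(
    data.frame(query_id = "q1", peptide_length = 60), "all_pass", seed = 2)
  dec <- filterHomology(ht$alignments)
  expect_true(dec$retained)

  ## knocking out one record via a forbidden description sinks the query
  aln <- ht$alignments
  aln$sdescription[2] <- "hypothetical protein"
  dec2 <- filterHomology(aln)
  expect_false(dec2$retained)
  expect_match(dec2$failures, "too_few_alignments")

  ## zero alignments: reported too_few
  dec3 <- filterHomology(aln[0, ], queryIds = "ghost")
  expect_false(dec3$retained)
  expect_identical(dec3$failures, "too_few_alignments")

  ## randomized 500-row table over 40 queries: identical to brute force
  big <- randomHomologyTable(500L, 40L, seed = 33L)
  mine <- filterHomology(big)
  oracle <- oracleHomologyFilter(big)
  expect_identical(setNames(mine$retained, mine$query_id)[names(oracle)],
                   oracle)

  ## order independence
  perm <- big[sample(nrow(big)), ]
  mineP <- filterHomology(perm)
  expect_mapequal(setNames(as.list(mineP$retained), mineP$query_id),
                  setNames(as.list(mine$retained), mine$query_id))
})

test_that("relaxing any single threshold never shrinks the retained set", {
  big <- randomHomologyTable(500L, 40L, seed = 44L)
  base <- filterHomology(big)
  baseSet <- base$query_id[base$retained]
  relaxed <- list(
    filterHomology(big, minIdentity = 85),
    filterHomology(big, minCoverage = 0.8),
    filterHomology(big, minAlignLength = 40L),
    filterHomology(big, minAlignments = 4L))
  for (r in relaxed)
    expect_true(all(baseSet %in% r$query_id[r$retained]))

  ## peptide-length relaxation on the ORF side
  chains <- lapply(45:55, function(p) makeChain(c("+", "+"),
                                                c(FALSE, TRUE), p))
  pass50 <- vapply(chains, function(ch)
    validateOrfChain(ch, minPeptide = 50L)$pass, logical(1))
  pass40 <- vapply(chains, function(ch)
    validateOrfChain(ch, minPeptide = 40L)$pass, logical(1))
  expect_true(all(pass40 >= pass50))
})

test_that("novel-model annotation composes ORF and homology decisions", {
  d <- syntheticDesign(nGenes = 8L, nTissues = 4L, seed = 19L,
                       modules = defaultModules(1L, 2L))
  gm <- generateGenomeAndModels(d)
  gmap <- transcriptGeneMap(gm$models)
  txIds <- names(gmap)

  ## plant coding sequence in half the candidates; ORF truth from the
  ## validated chain engine, homology truth from the generator labels
  coding <- txIds[1:4]
  genome <- plantCodingSequences(gm$genome, gm$models, coding, seed = 20L)
  pep <- vapply(txIds, function(tx)
    nchar(chainPeptide(longestOrfsPerExon(genome, gm$models, tx))),
    integer(1))
  scen <- rep(c("all_pass", "gap_fail"), length.out = length(txIds))
  ht <- simulateHomologyTable(
    data.frame(query_id = txIds, peptide_length = pmax(60L, pep)),
    scen, seed = 21L)

  res <- annotateNovelModels(genome, gm$models, ht$alignments)
  dec <- res$decisions

  orfTruth <- vapply(txIds, function(tx)
    validateOrfChain(longestOrfsPerExon(genome, gm$models, tx))$pass,
    logical(1))
  homTruth <- setNames(ht$queryLabels$retain, ht$queryLabels$query_id)
  ret <- setNames(dec$retained, dec$transcript_id)
  expect_identical(ret, orfTruth & homTruth[txIds])
  expect_true(all(ret[coding[scen[1:4] == "all_pass"]]))

  ## engineered coding candidates pass the ORF criteria by construction
  expect_true(all(dec$orf_pass[dec$transcript_id %in% coding]))

  ## a candidate passing ORF but failing homology reports only homology
  ## failures
  onlyHom <- dec[dec$orf_pass & !dec$homology_pass, ]
  if (nrow(onlyHom)) {
    expect_true(all(onlyHom$orf_failures == ""))
    expect_true(all(onlyHom$homology_failures != ""))
  }

  ## every rejected candidate lists at least one failure code
  rej <- dec[!dec$retained, ]
  expect_true(all(rej$orf_failures != "" | rej$homology_failures != ""))
})
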