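test_that("genome and model generation is deterministic and well-formed", {
  d <- syntheticDesign(nGenes = 10L, nTissues = 4L, seed = 42L,
                       modules = defaultModules(2L, 3L),
                       transcriptsPerGene = 2L)
  gm1 <- generateGenomeAndModels(d)
  gm2 <- generateGenomeAndModels(d)

  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  writeGenomeFasta(gm1$genome, f1); writeGenomeFasta(gm2$genome, f2)
  writeModelsGTF(gm1$models, g1); writeModelsGTF(gm2$models, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  md <- S4Vectors::mcols(gm1$models)
  expect_length(unique(md$transcript_id), 20L)   # 10 genes x 2 isoforms
  expect_length(unique(md$gene_id), 10L)
  expect_true(all(table(unique(data.frame(md$gene_id, md$transcript_id))[, 1]) >= 1))
  expect_setequal(unique(as.character(GenomicRanges::strand(gm1$models))),
                  c("+", "-"))

  ## exons lie within their chromosome and are ordered, non-overlapping
  for (tx in unique(md$transcript_id)) {
    ex <- gm1$models[md$transcript_id == tx]
    ex <- ex[order(GenomicRanges::start(ex))]
    expect_true(all(GenomicRanges::end(ex) <=
      Biostrings::width(gm1$genome)[match(as.character(GenomicRanges::seqnames(ex)),
                                          names(gm1$genome))]))
    if (length(ex) > 1)
      expect_true(all(GenomicRanges::start(ex)[-1] >
                        GenomicRanges::end(ex)[-length(ex)]))
  }
  expect_error(generateGenomeAndModels(
    syntheticDesign(nGenes = 0L, modules = defaultModules(0, 0))))
})

test_that("minus-strand spliced sequences match a per-base extraction oracle", {
  d <- smallDesign(seed = 7L)
  gm <- generateGenomeAndModels(d)
  txs <- transcriptSequences(gm$genome, gm$models)
  md <- S4Vectors::mcols(gm$models)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  minusTx <- unique(md$transcript_id[as.character(
    GenomicRanges::strand(gm$models)) == "-"])
  for (tx in head(minusTx, 5)) {
    ex <- gm$models[md$transcript_id == tx]
    ex <- ex[order(GenomicRanges::start(ex))]
    chromSeq <- strsplit(as.character(
      gm$genome[[as.character(GenomicRanges::seqnames(ex))[1]]]), "")[[1]]
    bases <- unlist(lapply(seq_along(ex), function(i)
      chromSeq[GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i]]))
    oracle <- paste(rev(unname(comp[bases])), collapse = "")
    expect_identical(as.character(txs[[tx]]), oracle)
  }
})

test_that("expression simulation plants the designed structure", {
  d0 <- smallDesign(seed = 3L, noiseSdLog = 0)
  se0 <- simulateExpression(d0)
  tpm0 <- SummarizedExperiment::assay(se0, "TPM")
  ## zero noise: all replicates of a tissue identical
  cd <- SummarizedExperiment::colData(se0)
  for (t in unique(cd$tissue)) {
    cols <- rownames(cd)[cd$tissue == t]
    expect_equal(tpm0[, cols[1]], tpm0[, cols[2]])
  }
  ## per-sample conservation
  expect_equal(unname(colSums(tpm0)), rep(1e6, ncol(tpm0)),
               tolerance = 1e-6)
  ## same-module genes share expected per-tissue means; housekeeping flat
  E <- expectedTissueMeans(d0)
  roles <- geneRoles(d0)
  g1 <- roles$gene_id[which(roles$module_id == "module01")]
  expect_true(all(apply(E[g1, ], 2, function(col) length(unique(col)) == 1)))
  hk <- roles$gene_id[roles$role == "housekeeping"][1]
  expect_equal(unname(E[hk, ]), rep(d0@housekeepingMeanTPM, d0@nTissues))
  ## module tissue outside the panel is rejected
  badMod <- defaultModules(1, 3)
  badMod$tissues <- "tissue99"
  expect_error(syntheticDesign(nGenes = 20, nTissues = 4, modules = badMod),
               "panel")
})

test_that("same-module genes correlate strongly across seeds", {
  rs <- vapply(1:100, function(s) {
    d <- syntheticDesign(nGenes = 12L, nTissues = 5L, replicates = 2L,
                         modules = defaultModules(2L, 4L),
                         housekeepingFraction = 0, noiseSdLog = 0.1,
                         seed = 1000L + s)
    se <- simulateExpression(d)
    tm <- tissueAverage(se)
    roles <- geneRoles(d)
    g <- roles$gene_id[which(roles$module_id == "module01")][1:2]
    cor(tm[g[1], ], tm[g[2], ])
  }, numeric(1))
  expect_gte(mean(rs), 0.95)
})

test_that("within-module correlation exceeds between-module correlation", {
  hits <- vapply(1:50, function(s) {
    d <- syntheticDesign(nGenes = 20L, nTissues = 6L, replicates = 2L,
                         modules = defaultModules(3L, 5L),
                         housekeepingFraction = 0, noiseSdLog = 0.1,
                         seed = 2000L + s)
    tm <- tissueAverage(simulateExpression(d))
    roles <- geneRoles(d)
    m1 <- roles$gene_id[which(roles$module_id == "module01")]
    m2 <- roles$gene_id[which(roles$module_id == "module02")]
    within <- cor(tm[m1[1], ], tm[m1[2], ])
    between <- cor(tm[m1[1], ], tm[m2[1], ])
    within > between
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("read simulation respects abundance, strand and error settings", {
  set.seed(11)
  txs <- Biostrings::DNAStringSet(c(
    tA = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
    tB = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")))

  ## single expressed transcript: every pair originates from it
  rd <- simulateReads(txs, c(tA = 1, tB = 0), nPairs = 200, readLen = 80,
                      seed = 5)
  expect_true(all(rd$truth$transcript_id == "tA"))

  ## error-free reads substring-match their source (stranded convention)
  src <- as.character(txs[rd$truth$transcript_id])
  expect_true(all(mapply(grepl, as.character(rd$r1), src, fixed = TRUE)))
  rc2 <- as.character(Biostrings::reverseComplement(rd$r2))
  expect_true(all(mapply(grepl, rc2, src, fixed = TRUE)))

  ## 3:1 abundance ratio recovered within 3 binomial sd
  rd2 <- simulateReads(txs, c(tA = 3, tB = 1), nPairs = 10000, readLen = 80,
                       seed = 6)
  nA <- sum(rd2$truth$transcript_id == "tA")
  p <- 0.75
  expect_lt(abs(nA - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))

  expect_error(simulateReads(txs, c(tA = 0, tB = 0), nPairs = 10), "zero")
  expect_error(simulateReads(txs, c(tA = 1, tB = 0), nPairs = 0), "nPairs")
})

test_that("homology tables carry correct single-violation truth labels", {
  queries <- data.frame(query_id = paste0("q", 1:8),
                        peptide_length = c(80, 80, 80, 53, 80, 80, 80, 80))
  scen <- c("all_pass", "identity_fail", "coverage_fail", "length_fail",
            "gap_fail", "description_fail", "genus_fail", "too_few")
  ht <- simulateHomologyTable(queries, scen, seed = 4L)

  expect_true(ht$queryLabels$retain[ht$queryLabels$scenario == "all_pass"])
  expect_true(all(!ht$queryLabels$retain[ht$queryLabels$scenario != "all_pass"]))

  ## the all_pass query: 5 records, a Bos subject, clean metrics
  ap <- ht$alignments[ht$alignments$query_id == "q1", ]
  expect_equal(nrow(ap), 5L)
  expect_true("Bos" %in% ap$sgenus)
  expect_true(all(ap$pident >= 90 & ap$gaps == 0 & ap$length >= 50))

  ## gap_fail: exactly one record violates, and only via gaps
  gf <- ht$recordLabels[ht$recordLabels$query_id == "q5", ]
  expect_equal(sum(!gf$valid), 1L)
  expect_equal(gf$violated[!gf$valid], "gaps")

  ## labels agree 100% with an independent re-implementation
  oracle <- oracleHomologyFilter(ht$alignments)
  got <- setNames(ht$queryLabels$retain, ht$queryLabels$query_id)
  expect_identical(got[names(oracle)], oracle)
})
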