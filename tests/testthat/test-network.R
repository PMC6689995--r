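test_that("tissue averaging equals a naive group-by oracle", {
  ## two replicates at 10 and 20 average to 15
  m <- matrix(c(10, 20), 1, 2, dimnames = list("g1", c("a", "b")))
  meta <- data.frame(sample = c("a", "b"), tissue = "liver")
  expect_equal(unname(tissueAverage(m, meta)[1, 1]), 15)

  ## single-replicate tissue: column equals the sample
  meta2 <- data.frame(sample = c("a", "b"), tissue = c("liver", "spleen"))
  tm2 <- tissueAverage(m, meta2)
  expect_equal(unname(tm2["g1", ]), c(10, 20))

  ## random 50 x 12 matrix with random grouping vs naive loop
  set.seed(91)
  mat <- matrix(runif(50 * 12, 0, 1000), 50, 12,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  meta3 <- data.frame(sample = colnames(mat),
                      tissue = sample(paste0("t", 1:4), 12, replace = TRUE))
  tm3 <- tissueAverage(mat, meta3)
  for (t in unique(meta3$tissue)) {
    cols <- meta3$sample[meta3$tissue == t]
    oracle <- apply(mat[, cols, drop = FALSE], 1, mean)
    expect_equal(tm3[, t], oracle)
  }

  ## unmapped sample errors with the offender named
  expect_error(tissueAverage(mat, meta3[-1, ]), "s1")
})

test_that("expression filter applies a strict TPM floor on the row max", {
  tm <- rbind(atBoundary = c(10, 3, 1),
              justAbove = c(10.5, 0, 0),
              low = c(2, 2, 2))
  colnames(tm) <- paste0("t", 1:3)
  kept <- expressionFilter(tm, minTpm = 10)
  expect_identical(rownames(kept), "justAbove")

  ## row-max oracle on a random matrix
  set.seed(92)
  m <- matrix(rlnorm(200 * 8, 1, 2), 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("t", 1:8)))
  kept2 <- expressionFilter(m, 10)
  oracle <- rownames(m)[apply(m, 1, max) > 10]
  expect_identical(rownames(kept2), oracle)

  expect_error(expressionFilter(tm, minTpm = 1e9), "threshold")
})

test_that("correlation graph matches the direct-formula oracle", {
  ## proportional profiles correlate exactly 1
  tm <- rbind(g1 = c(2, 4, 6), g2 = c(1, 2, 3), g3 = c(6, 1, 2))
  colnames(tm) <- paste0("t", 1:3)
  gr <- correlationGraph(tm, rMin = 0.99)
  expect_equal(nrow(graphEdges(gr)), 1L)
  expect_identical(graphEdges(gr)$gene_a, "g1")
  expect_identical(graphEdges(gr)$gene_b, "g2")

  ## constant-profile gene excluded and reported
  tm2 <- rbind(tm, flat = c(5, 5, 5))
  gr2 <- correlationGraph(tm2, rMin = 0.5)
  expect_identical(gr2@zeroVariance, "flat")
  expect_false("flat" %in% graphNodes(gr2))

  ## adjacency identical to a naive covariance/sd oracle
  set.seed(93)
  m <- matrix(rlnorm(20 * 10, 2, 1), 20, 10,
              dimnames = list(paste0("g", sprintf("%02d", 1:20)),
                              paste0("t", 1:10)))
  gr3 <- correlationGraph(m, rMin = 0.5)
  edges <- graphEdges(gr3)
  got <- paste(edges$gene_a, edges$gene_b)
  oracle <- character(0)
  genes <- rownames(m)
  for (i in 1:19) for (j in (i + 1):20) {
    if (oracleCor(m[i, ], m[j, ]) >= 0.5)
      oracle <- c(oracle, paste(genes[i], genes[j]))
  }
  expect_setequal(got, oracle)
  ## edge weights agree with the oracle formula
  for (k in seq_len(nrow(edges)))
    expect_equal(edges$r[k], oracleCor(m[edges$gene_a[k], ],
                                       m[edges$gene_b[k], ]),
                 tolerance = 1e-12)

  expect_error(correlationGraph(m[, 1:2, drop = FALSE], 0.8), "3 tissues")
})

test_that("MCL resolves symmetric and disconnected structures", {
  mkGraph <- function(edges, nodes) {
    new("CoexpressionGraph", nodes = nodes,
        edges = edges[order(edges$gene_a, edges$gene_b), ],
        rMin = 0.8, zeroVariance = character(0))
  }
  clique <- function(members, w = 0.9) {
    do.call(rbind, lapply(seq_along(members)[-length(members)], function(i)
      data.frame(gene_a = members[i],
                 gene_b = members[(i + 1):length(members)],
                 r = w, stringsAsFactors = FALSE)))
  }

  ## two disjoint 4-cliques: exactly their two clusters
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  g <- mkGraph(rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4))),
               nodes)
  ca <- mclCluster(g, minClusterSize = 1L)
  expect_length(clusterSets(ca), 2L)
  expect_setequal(clusterSets(ca)[[1]], paste0("a", 1:4))
  expect_setequal(clusterSets(ca)[[2]], paste0("b", 1:4))

  ## complete equal-weight graph on 5 nodes: one cluster
  g5 <- mkGraph(clique(paste0("n", 1:5), 0.85), paste0("n", 1:5))
  ca5 <- mclCluster(g5, minClusterSize = 1L)
  expect_length(clusterSets(ca5), 1L)

  ## columns remain stochastic after every recorded inflation step
  expect_true(all(ca5@maxColSumDeviation <= 1e-9))
  ## partition covers all nodes disjointly
  mem <- clusterMembership(ca5)
  expect_setequal(names(mem), paste0("n", 1:5))
})

test_that("MCL partitions equal the frozen reference implementation", {
  refDir <- system.file("extdata", "mcl_reference", package = "atlasforge")
  ref <- read.delim(file.path(refDir, "reference_partitions.tsv"),
                    stringsAsFactors = FALSE)
  graphs <- sprintf("graph%02d", 1:12)
  expect_setequal(unique(ref$graph), graphs)
  for (g in graphs) {
    e <- read.delim(file.path(refDir, paste0(g, ".tsv")),
                    stringsAsFactors = FALSE)
    nodes <- sort(unique(c(e$gene_a, e$gene_b)))
    gr <- new("CoexpressionGraph", nodes = nodes,
              edges = e[order(e$gene_a, e$gene_b), ], rMin = 0.8,
              zeroVariance = character(0))
    ca <- mclCluster(gr, inflation = 2.2, minClusterSize = 1L)
    mine <- sort(vapply(clusterSets(ca), function(s)
      paste(sort(s), collapse = ","), character(1)))
    rp <- ref[ref$graph == g, ]
    theirs <- sort(vapply(split(rp$node, rp$cluster), function(s)
      paste(sort(s), collapse = ","), character(1)))
    expect_identical(unname(mine), unname(theirs), label = g)
    expect_true(all(ca@maxColSumDeviation <= 1e-9))
  }
})

test_that("cluster postprocessing sizes, filters and numbers correctly", {
  part <- list(c("d", "e", "f", "g", "h", "i", "j"),      # size 7
               c("a", "b", "c", "x", "y", "z", "w", "v", "u", "t"),  # 10
               c("k", "l", "m", "n"))                     # size 4
  ca <- postprocessClusters(part, minSize = 5L)
  expect_equal(lengths(clusterSets(ca)), c(`1` = 10L, `2` = 7L))
  expect_length(smallClusters(ca), 1L)
  expect_setequal(smallClusters(ca)[[1]], c("k", "l", "m", "n"))

  ## nothing excluded: pure renumbering by (-size, min member)
  part2 <- list(paste0("z", 1:5), paste0("a", 1:5), paste0("m", 1:6))
  ca2 <- postprocessClusters(part2, minSize = 5L)
  expect_equal(clusterSets(ca2)[["1"]], sort(paste0("m", 1:6)))
  expect_equal(clusterSets(ca2)[["2"]], sort(paste0("a", 1:5)))

  ## random partitions match a sort oracle
  set.seed(94)
  for (i in 1:10) {
    sizes <- sample(1:12, 6, replace = TRUE)
    pool <- paste0("g", sprintf("%03d", sample(500, sum(sizes))))
    part3 <- split(pool, rep(seq_along(sizes), sizes))
    ca3 <- postprocessClusters(part3, minSize = 5L)
    keyed <- lapply(unname(part3), sort)
    ord <- order(-lengths(keyed),
                 vapply(keyed, `[`, character(1), 1L))
    oracle <- keyed[ord]
    oracle <- oracle[lengths(oracle) >= 5L]
    expect_identical(unname(clusterSets(ca3)), oracle)
  }
})

test_that("graph export writes edges and cluster attributes", {
  e <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                  r = c(0.9, 0.85, 0.95), stringsAsFactors = FALSE)
  gr <- new("CoexpressionGraph", nodes = c("a", "b", "c"), edges = e,
            rMin = 0.8, zeroVariance = character(0))
  ca <- postprocessClusters(list(c("a", "b", "c")), minSize = 1L)
  ef <- tempfile(fileext = ".tsv")
  gf <- tempfile(fileext = ".graphml")
  writeGraph(gr, ef, gf, clusters = ca)
  back <- read.delim(ef, stringsAsFactors = FALSE)
  expect_equal(back, e)
  xml <- readLines(gf)
  expect_true(any(grepl("graphml", xml)))
  expect_true(any(grepl("cluster", xml)))
})
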