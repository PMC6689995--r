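#' Markov clustering of a co-expression graph
#'
#' From-scratch MCL. The weighted adjacency (edge weights are the
#' correlations) gets a self-loop of weight \code{selfLoop} on every
#' node and is column-normalized into a transition matrix. Each
#' iteration applies expansion (matrix power \code{expansion}), then
#' inflation (entry-wise power \code{inflation} followed by column
#' renormalization), then pruning of entries below
#' \code{pruneThreshold} with another renormalization. Iteration stops
#' when the largest entry change falls below \code{tol}.
#'
#' Clusters are read off the limit matrix: attractors are nodes with
#' positive diagonal mass; attractors sharing positive mass in each
#' other's rows or columns form one attractor system; every node joins
#' the system holding positive mass in its column. A node attracted to
#' several systems goes to the one with the larger attractor mass (ties
#' to the system containing the lexicographically smallest member).
#' Results are deterministic for a fixed node ordering.
#'
#' @param graph a \linkS4class{CoexpressionGraph}.
#' @param inflation inflation exponent (> 1, default 2.2); larger values
#'   give finer clusters.
#' @param expansion expansion power (default 2).
#' @param pruneThreshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param tol convergence tolerance on the max entry change
#'   (default 1e-6).
#' @param maxIter iteration cap (default 200); non-convergence returns
#'   the current interpretation with a warning.
#' @param selfLoop self-loop weight added before normalization
#'   (default 1).
#' @param minClusterSize minimum retained cluster size applied by
#'   [postprocessClusters()] (default 5).
#' @return a \linkS4class{ClusterAssignment}.
#' @export
mclCluster <- function(graph, inflation = 2.2, expansion = 2L,
                       pruneThreshold = 1e-5, tol = 1e-6,
                       maxIter = 200L, selfLoop = 1,
                       minClusterSize = 5L) {
  stopifnot(is(graph, "CoexpressionGraph"))
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- graph@nodes
  n <- length(nodes)
  if (!n) stop("graph has no nodes")

  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph@edges
  if (nrow(e)) {
    ia <- match(e$gene_a, nodes)
    ib <- match(e$gene_b, nodes)
    M[cbind(ia, ib)] <- e$r
    M[cbind(ib, ia)] <- e$r
  }
  diag(M) <- selfLoop
  M <- sweep(M, 2L, colSums(M), "/")

  colDev <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    prev <- M
    for (i in seq_len(expansion - 1L)) M <- M %*% prev  # expansion
    M <- M^inflation                                    # inflation
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2L, cs, "/")
    colDev <- c(colDev, max(abs(colSums(M) - 1)))
    M[M < pruneThreshold] <- 0                          # pruning
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2L, cs, "/")
    if (max(abs(M - prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", maxIter,
            " iterations; interpreting the current matrix")

  partition <- .interpretMCL(M, nodes)
  postprocessClusters(partition, minSize = minClusterSize,
                      inflation = inflation, iterations = iter,
                      converged = converged, colSumDeviation = colDev)
}

## Attractor-based interpretation of the MCL limit matrix.
.interpretMCL <- function(M, nodes) {
  n <- length(nodes)
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- seq_len(n)  # degenerate safeguard
  ## attractor systems: connected components of the attractor-attractor
  ## nonzero pattern (symmetrized)
  A <- (M[attractors, attractors, drop = FALSE] > 0) |
    t(M[attractors, attractors, drop = FALSE] > 0)
  sysId <- integer(length(attractors))
  cur <- 0L
  for (i in seq_along(attractors)) {
    if (sysId[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (sysId[v] > 0L) next
      sysId[v] <- cur
      queue <- c(queue, which(A[v, ] & sysId == 0L))
    }
  }
  nSys <- cur
  ## per-node mass received from each system (rows of attractors)
  mass <- matrix(0, nSys, n)
  for (s in seq_len(nSys))
    mass[s, ] <- colSums(M[attractors[sysId == s], , drop = FALSE])
  ## deterministic tie-break: systems ordered by smallest member name
  sysMin <- vapply(seq_len(nSys), function(s)
    min(nodes[attractors[sysId == s]]), character(1))
  ord <- order(sysMin)
  mass <- mass[ord, , drop = FALSE]
  assign <- apply(mass, 2L, function(col) {
    if (all(col == 0)) NA_integer_ else which.max(col)
  })
  assign[is.na(assign)] <- nSys + seq_len(sum(is.na(assign)))  # isolated
  split(nodes, assign)
}

#' Size-order and size-filter a raw partition
#'
#' Clusters below \code{minSize} move to the set-aside small list;
#' survivors are renumbered 1..K by non-increasing size, ties broken by
#' the smallest lexicographic member identifier.
#'
#' @param partition list of character vectors covering all nodes.
#' @param minSize minimum retained cluster size (default 5).
#' @param inflation,iterations,converged,colSumDeviation diagnostics
#'   recorded in the result (defaults for standalone use).
#' @return a \linkS4class{ClusterAssignment}.
#' @export
postprocessClusters <- function(partition, minSize = 5L, inflation = NA_real_,
                                iterations = 0L, converged = TRUE,
                                colSumDeviation = numeric(0)) {
  partition <- lapply(partition, function(x) sort(as.character(x)))
  sizes <- lengths(partition)
  minMember <- vapply(partition, function(x)
    if (length(x)) x[[1L]] else "", character(1))
  ord <- order(-sizes, minMember)
  partition <- partition[ord]
  sizes <- sizes[ord]
  keep <- sizes >= minSize
  retained <- partition[keep]
  names(retained) <- as.character(seq_along(retained))
  new("ClusterAssignment", clusters = retained,
      small = unname(partition[!keep]), inflation = inflation,
      minClusterSize = as.integer(minSize),
      iterations = as.integer(iterations), converged = converged,
      maxColSumDeviation = colSumDeviation)
}

#' Agreement between recovered clusters and planted modules
#'
#' Adjusted Rand index between a cluster assignment and the planted
#' module labels, computed over planted module member genes only (other
#' genes carry no planted label). Genes whose cluster fell below the
#' minimum size count as one extra "unclustered" label.
#'
#' @param assignment a \linkS4class{ClusterAssignment}.
#' @param roles data.frame from [geneRoles()] (columns \code{gene_id},
#'   \code{module_id}).
#' @return adjusted Rand index in [-1, 1].
#' @export
plantedRecoveryARI <- function(assignment, roles) {
  mod <- roles[!is.na(roles$module_id), ]
  mem <- clusterMembership(assignment)
  rec <- mem[mod$gene_id]
  rec[is.na(rec)] <- 0L   # unclustered / set-aside
  adjustedRandIndex(rec, mod$module_id)
}
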