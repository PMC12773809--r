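# Seed expansion on an interaction network (hypergeometric over-connectivity
# and random-walk-with-restart propagation with permutation nulls) and the
# four-pillar network stability suite. Distances, components, betweenness
# and communities come from igraph; all topology metrics are computed on the
# unweighted simple graph (interaction confidences are not distances); edge
# weights enter only the propagation normalization.

netGraph <- function(net) {
  if (is(net, "InteractionNetwork")) net@graph
  else if (igraph::is_igraph(net)) net
  else stop("expected an InteractionNetwork or igraph object")
}

#' Read an interaction edge list
#'
#' Tab-delimited \code{node1 node2 weight} with an optional header;
#' STRING-export column aliases (\code{protein1 protein2 combined_score})
#' are recognized. Edges with weight below \code{scoreThreshold} are
#' dropped (default 0: trust the input).
#'
#' @param path file path.
#' @param scoreThreshold minimum retained edge weight.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readEdgeList <- function(path, scoreThreshold = 0) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "[\t ]+")[[1]]
  hasHeader <- length(first) >= 2L &&
    (tolower(first[1]) %in% c("node1", "protein1", "from", "source") ||
     (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3])))))
  df <- read.delim(path, header = hasHeader, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  w <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else rep(1, nrow(df))
  keep <- w >= scoreThreshold
  interactionNetwork(data.frame(df[[1L]][keep], df[[2L]][keep], w[keep]))
}

#' Write an interaction network as an edge-list TSV
#' @param net an \linkS4class{InteractionNetwork}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path) {
  g <- netGraph(net)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  write.table(data.frame(node1 = el[, 1L], node2 = el[, 2L], weight = w),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hypergeometric over-connectivity scoring of hidden nodes
#'
#' For each non-seed node v with degree k and x seed neighbors, the
#' upper-tail hypergeometric probability of drawing at least x seeds in k
#' draws from a population of N = |nodes| - 1 nodes containing K = |seeds|
#' successes (the tested node is excluded from the population). P-values
#' are adjusted over all evaluated nodes; nodes with adjusted p below
#' \code{alpha} are flagged, and the score is \code{-log10(adjusted p)}.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param seeds character seed node IDs; the overlap with the network must
#'   be nonempty.
#' @param alpha significance cutoff on adjusted p (default 0.05).
#' @param adjust \code{"BH"} (default) or \code{"bonferroni"}.
#' @param includeSeeds also score seed nodes (each seed then sees K - 1
#'   remaining successes); default FALSE.
#' @return data.frame (node, degree, seedNeighbors, pvalue, padj, score,
#'   retained, method), ordered by p-value.
#' @examples
#' g <- igraph::make_ring(10)
#' igraph::V(g)$name <- letters[1:10]
#' hiddenNodes(interactionNetwork(g), seeds = c("a", "c"))
#' @export
hiddenNodes <- function(net, seeds, alpha = 0.05, adjust = c("BH", "bonferroni"),
                        includeSeeds = FALSE) {
  adjust <- match.arg(adjust)
  g <- netGraph(net)
  nodes <- igraph::V(g)$name
  seeds <- intersect(unique(seeds), nodes)
  if (!length(seeds)) stop("seed set has empty overlap with the network")
  isSeed <- nodes %in% seeds
  cand <- if (includeSeeds) nodes else nodes[!isSeed]
  if (!length(cand)) stop("no candidate nodes to score")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1                                  # unweighted adjacency
  deg <- Matrix::rowSums(A)
  seedHits <- as.numeric(A %*% isSeed)
  N <- length(nodes) - 1L
  K <- length(seeds)
  idx <- match(cand, nodes)
  Kv <- ifelse(isSeed[idx], K - 1L, K)        # exclude the tested node
  k <- deg[idx]
  x <- seedHits[idx]
  p <- phyper(x - 1, Kv, N - Kv, k, lower.tail = FALSE)
  padj <- p.adjust(p, method = adjust)
  out <- data.frame(node = cand, degree = as.integer(k),
                    seedNeighbors = as.integer(x), pvalue = p, padj = padj,
                    score = -log10(padj), retained = padj < alpha,
                    method = "HN", row.names = NULL)
  out[order(out$pvalue, out$node), , drop = FALSE]
}

# column-stochastic (degree-normalized) weighted adjacency
columnStochastic <- function(g) {
  A <- igraph::as_adjacency_matrix(g, attr = if (is.null(igraph::E(g)$weight))
    NULL else "weight", sparse = TRUE)
  s <- Matrix::colSums(A)
  s[s == 0] <- 1
  A %*% Matrix::Diagonal(x = 1 / s)
}

propagate <- function(W, F0, restart, tol = 1e-6, maxIter = 10000L) {
  Fm <- F0
  for (i in seq_len(maxIter)) {
    Fn <- (1 - restart) * (W %*% Fm) + restart * F0
    # L1 convergence, per propagation column
    if (max(Matrix::colSums(abs(Fn - Fm))) < tol) return(as.matrix(Fn))
    Fm <- Fn
  }
  as.matrix(Fm)
}

#' Network propagation (random walk with restart) seed expansion
#'
#' Starts from uniform mass on the seeds and iterates
#' \code{F <- (1 - restart) * W F + restart * F0} with W the
#' column-stochastic weighted adjacency until the L1 change drops below
#' \code{tol}; mass is conserved at every step. Per-node empirical p-values
#' come from \code{nPerm} degree-matched random seed sets (nodes resampled
#' within 10 degree-quantile bins):
#' \code{p = (1 + #[F_null >= F_obs]) / (nPerm + 1)}. P-values are
#' BH-adjusted, scores are \code{-log10(adjusted p)}, and the top
#' \code{ceiling(topFrac * #scored nodes)} nodes by score are flagged as
#' retained.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param seeds character seed IDs.
#' @param restart restart probability in (0, 1].
#' @param tol convergence tolerance on the max-norm change.
#' @param nPerm permutation count for the null.
#' @param topFrac retained fraction (default 0.01).
#' @param seed RNG seed.
#' @param nBins degree-quantile bins for the null (default 10).
#' @return data.frame (node, degree, flow, pvalue, padj, score, retained,
#'   method), non-seed nodes only, ordered by decreasing score.
#' @export
networkPropagation <- function(net, seeds, restart = 0.5, tol = 1e-6,
                               nPerm = 1000L, topFrac = 0.01, seed = 1L,
                               nBins = 10L) {
  if (restart <= 0 || restart > 1) stop("restart must lie in (0, 1]")
  g <- netGraph(net)
  nodes <- igraph::V(g)$name
  seeds <- intersect(unique(seeds), nodes)
  if (!length(seeds)) stop("seed set has empty overlap with the network")
  n <- length(nodes)
  W <- columnStochastic(g)
  seedIdx <- match(seeds, nodes)
  F0 <- Matrix::sparseVector(rep(1 / length(seeds), length(seeds)),
                             seedIdx, n)
  F0 <- Matrix::Matrix(as.numeric(F0), ncol = 1, sparse = FALSE)
  Fobs <- drop(propagate(W, F0, restart, tol))
  deg <- igraph::degree(g)
  br <- unique(quantile(deg, probs = seq(0, 1, length.out = nBins + 1L)))
  bin <- if (length(br) < 2L) rep(1L, n)
         else cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
  seedBins <- bin[seedIdx]
  nullGE <- numeric(n)           # per node: #perms with F_null >= F_obs
  withSeed(seed, {
    F0null <- matrix(0, n, nPerm)
    for (b in seq_len(nPerm)) {
      draw <- unlist(lapply(unique(seedBins), function(bb) {
        pool <- which(bin == bb)
        need <- sum(seedBins == bb)
        if (length(pool) == 1L) pool else sample(pool, need,
                                                 replace = need > length(pool))
      }), use.names = FALSE)
      F0null[draw, b] <- F0null[draw, b] + 1 / length(seedIdx)
    }
    Fnull <- propagate(W, Matrix::Matrix(F0null, sparse = TRUE), restart, tol)
    nullGE <- rowSums(Fnull >= Fobs - 1e-15)
  })
  p <- (1 + nullGE) / (nPerm + 1)
  isSeed <- nodes %in% seeds
  keep <- !isSeed
  padj <- p.adjust(p[keep], method = "BH")
  score <- -log10(padj)
  nTop <- ceiling(topFrac * sum(keep))
  ordScore <- order(-score, -Fobs[keep])
  retained <- logical(sum(keep))
  retained[ordScore[seq_len(min(nTop, length(ordScore)))]] <- TRUE
  out <- data.frame(node = nodes[keep], degree = as.integer(deg[keep]),
                    flow = Fobs[keep], pvalue = p[keep], padj = padj,
                    score = score, retained = retained, method = "NP",
                    row.names = NULL)
  out <- out[order(-out$score, -out$flow, out$node), , drop = FALSE]
  attr(out, "flowAll") <- setNames(Fobs, nodes)   # incl. seed nodes
  out
}

#' Network robustness under random node removal
#'
#' For each removal fraction f, performs \code{reps} random deletions of
#' \code{floor(f * n)} nodes and records the ratio of the post-removal
#' largest connected component to the original LCC size. The overall score
#' is the unweighted mean of the per-fraction mean ratios.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param fractions removal fractions (default 0.05 to 0.50 by 0.05); all
#'   must be < 1.
#' @param reps simulations per fraction (default 20).
#' @param seed RNG seed.
#' @return List with \code{curve} (data.frame fraction, meanLCCRatio) and
#'   \code{score}.
#' @export
robustness <- function(net, fractions = seq(0.05, 0.50, by = 0.05),
                       reps = 20L, seed = 1L) {
  if (any(fractions >= 1) || any(fractions < 0))
    stop("removal fractions must lie in [0, 1)")
  g <- netGraph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("robustness simulation needs at least 2 nodes")
  lcc0 <- max(igraph::components(g)$csize)
  withSeed(seed, {
    curve <- vapply(fractions, function(f) {
      nRemove <- floor(f * n)
      mean(vapply(seq_len(reps), function(r) {
        keep <- igraph::delete_vertices(g, sample.int(n, nRemove))
        if (igraph::vcount(keep) == 0L) return(0)
        max(igraph::components(keep)$csize) / lcc0
      }, numeric(1)))
    }, numeric(1))
    list(curve = data.frame(fraction = fractions, meanLCCRatio = curve),
         score = mean(curve))
  })
}

#' Global efficiency
#'
#' \code{E = 1 / (N (N - 1)) * sum_{i != j} 1 / d(i, j)} on the unweighted
#' graph, with unreachable pairs contributing 0.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @return Efficiency in [0, 1].
#' @export
globalEfficiency <- function(net) {
  g <- netGraph(net)
  if (igraph::vcount(g) < 2L) stop("global efficiency needs >= 2 nodes")
  D <- igraph::distances(g, weights = NA)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (nrow(D) * (nrow(D) - 1L))
}

#' Node criticality by global-efficiency drop
#'
#' \code{criticality(v) = (E(G) - E(G - v)) / E(G)}, with the reduced
#' efficiency computed on the remaining node set; negative values mean the
#' deletion raises efficiency.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @return Named numeric vector over nodes.
#' @export
nodeCriticality <- function(net) {
  g <- netGraph(net)
  E0 <- globalEfficiency(g)
  if (E0 == 0) stop("criticality undefined: graph has zero efficiency")
  vs <- igraph::V(g)$name
  out <- vapply(vs, function(v) {
    (E0 - globalEfficiency(igraph::delete_vertices(g, v))) / E0
  }, numeric(1))
  setNames(out, vs)
}

#' Structural stability metrics
#'
#' Average path length over connected pairs within the largest connected
#' component; mean local clustering coefficient (nodes of degree < 2
#' contribute 0); modularity Q with its community partition from
#' deterministic greedy agglomeration (seedless; a seeded Louvain
#' alternative is available via \code{method = "louvain"}); Freeman degree
#' centralization \code{sum(dmax - d) / ((N - 1)(N - 2))}; and betweenness
#' centralization \code{sum(b'max - b') / (N - 1)} on [0,1]-normalized
#' betweenness.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param method community detection: \code{"greedy"} (deterministic,
#'   default) or \code{"louvain"} (stochastic, seeded).
#' @param seed seed for \code{method = "louvain"}.
#' @return List: avgPathLength, clustering, modularity, communities
#'   (membership vector), degreeCentralization, betweennessCentralization.
#' @export
structuralMetrics <- function(net, method = c("greedy", "louvain"),
                              seed = 1L) {
  method <- match.arg(method)
  g <- netGraph(net)
  n <- igraph::vcount(g)
  if (n < 3L) stop("structural metrics need >= 3 nodes")
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  apl <- igraph::mean_distance(lcc, weights = NA)
  ltrans <- igraph::transitivity(g, type = "local", isolates = "zero")
  clustering <- mean(ltrans)
  memb <- if (method == "greedy")
    igraph::cluster_fast_greedy(g, weights = NULL)
  else withSeed(seed, igraph::cluster_louvain(g))
  Q <- igraph::modularity(g, igraph::membership(memb))
  deg <- igraph::degree(g)
  degCent <- sum(max(deg) - deg) / ((n - 1) * (n - 2))
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  btwCent <- sum(max(btw) - btw) / (n - 1)
  list(avgPathLength = apl, clustering = clustering, modularity = Q,
       communities = setNames(as.integer(igraph::membership(memb)),
                              igraph::V(g)$name),
       degreeCentralization = degCent,
       betweennessCentralization = btwCent)
}

#' Regulator-versus-rest connectivity statistics
#'
#' Degree ratio = mean degree of regulator nodes / mean degree of the
#' remaining nodes (a ratio > 1 means regulators are more highly
#' connected), plus mean normalized betweenness for both groups.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param regulators character regulator node IDs; defaults to the
#'   network's own flags.
#' @return List: degreeRatio, regulatorMeanBetweenness,
#'   nonRegulatorMeanBetweenness, nRegulators.
#' @export
regulatorStats <- function(net, regulators = NULL) {
  g <- netGraph(net)
  if (is.null(regulators) && is(net, "InteractionNetwork"))
    regulators <- net@regulators
  nodes <- igraph::V(g)$name
  regulators <- intersect(unique(regulators), nodes)
  others <- setdiff(nodes, regulators)
  if (!length(regulators) || !length(others))
    stop("both regulator and non-regulator sets must be nonempty")
  deg <- igraph::degree(g)
  if (mean(deg[others]) == 0) stop("non-regulator mean degree is zero")
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  list(degreeRatio = mean(deg[regulators]) / mean(deg[others]),
       regulatorMeanBetweenness = mean(btw[regulators]),
       nonRegulatorMeanBetweenness = mean(btw[others]),
       nRegulators = length(regulators))
}

#' Four-pillar network stability report
#'
#' Bundles the robustness curve and score, per-node criticality, the
#' structural metrics, and (when regulators are supplied or flagged on the
#' network) the regulator statistics.
#'
#' @param net an \linkS4class{InteractionNetwork} (or igraph).
#' @param regulators optional regulator IDs.
#' @param fractions,reps,seed robustness simulation control.
#' @return A \code{StabilityReport} list with elements \code{robustness},
#'   \code{criticality}, \code{structural}, \code{regulator} (or NULL).
#' @export
stabilityReport <- function(net, regulators = NULL,
                            fractions = seq(0.05, 0.50, by = 0.05),
                            reps = 20L, seed = 1L) {
  if (is.null(regulators) && is(net, "InteractionNetwork") &&
      length(net@regulators)) regulators <- net@regulators
  rep_ <- list(
    robustness = robustness(net, fractions = fractions, reps = reps,
                            seed = seed),
    criticality = nodeCriticality(net),
    structural = structuralMetrics(net),
    regulator = if (length(regulators)) regulatorStats(net, regulators)
                else NULL)
  class(rep_) <- "StabilityReport"
  rep_
}

#' @export
print.StabilityReport <- function(x, ...) {
  s <- x$structural
  cat("StabilityReport\n")
  cat(sprintf("  robustness score:          %.3f\n", x$robustness$score))
  cat(sprintf("  average path length (LCC): %.3f\n", s$avgPathLength))
  cat(sprintf("  clustering coefficient:    %.3f\n", s$clustering))
  cat(sprintf("  modularity Q:              %.3f\n", s$modularity))
  cat(sprintf("  degree centralization:     %.3f\n",
              s$degreeCentralization))
  cat(sprintf("  betweenness centralization:%.3f\n",
              s$betweennessCentralization))
  if (!is.null(x$regulator))
    cat(sprintf("  regulator degree ratio:    %.3f\n",
                x$regulator$degreeRatio))
  invisible(x)
}

#' Write a stability report as JSON
#' @param report a \code{StabilityReport}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeStabilityJSON <- function(report, path) {
  jsonlite::write_json(list(
    robustnessScore = report$robustness$score,
    robustnessCurve = report$robustness$curve,
    criticality = as.list(report$criticality),
    structural = report$structural[c("avgPathLength", "clustering",
                                     "modularity", "degreeCentralization",
                                     "betweennessCentralization")],
    regulator = report$regulator), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
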