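# Shared fixtures and independent oracles, all built in code.

# two-class matrix with nSig informative features (class shift delta)
makeSignalMatrix <- function(n = 60, p = 40, nSig = 5, delta = 1.5,
                             seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("case", "control"), length.out = n))
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                sprintf("f%03d", seq_len(p))))
    if (nSig > 0)
      X[y == "case", seq_len(nSig)] <- X[y == "case", seq_len(nSig)] + delta
    list(X = X, y = y, signal = colnames(X)[seq_len(nSig)])
  })
}

# small three-block synthetic cohort (fast defaults for unit tests)
smallSimConfig <- function(nSamples = 60, seed = 1, nSignature = 8L,
                           effectSize = 1.5, ...) {
  simConfig(nSamples = nSamples, effectSize = effectSize,
            blocks = list(
              methylation = list(nFeatures = 60L, nSignature = nSignature,
                                 noiseSd = 1),
              expression = list(nFeatures = 60L, nSignature = nSignature,
                                noiseSd = 1, nbDispersion = 0.5,
                                libsizeSd = 0.3),
              proteomics = list(nFeatures = 40L, nSignature = nSignature,
                                noiseSd = 1)),
            seed = seed, ...)
}

namedGraph <- function(g, prefix = "v") {
  igraph::V(g)$name <- sprintf("%s%02d", prefix,
                               seq_len(igraph::vcount(g)))
  g
}

# independent hypergeometric upper-tail oracle by explicit enumeration
bruteHyperTail <- function(x, K, N, k) {
  xs <- seq(max(0, k - (N - K)), min(k, K))
  xs <- xs[xs >= x]
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, k - xs)) / choose(N, k)
}

# direct linear-solve oracle for random walk with restart
solveRWR <- function(g, seeds, restart) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, attr = if (is.null(igraph::E(g)$weight))
    NULL else "weight", sparse = FALSE)
  W <- A %*% diag(1 / colSums(A))
  F0 <- rep(0, n)
  F0[match(seeds, igraph::V(g)$name)] <- 1 / length(seeds)
  setNames(restart * solve(diag(n) - (1 - restart) * W, F0),
           igraph::V(g)$name)
}

# random connected named graph for oracle suites
randomConnectedGraph <- function(n, pEdge, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, pEdge)
      if (igraph::is_connected(g)) break
    }
    namedGraph(g, "n")
  })
}
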