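test_that("hidden-nodes p-value matches the worked hypergeometric example", {
  # 11 nodes: candidate v with degree 4, 2 of 3 seeds among its neighbors;
  # population N = 10, K = 3 -> upper tail P(X >= 2) = 1/3
  edges <- rbind(c("v", "s1"), c("v", "s2"), c("v", "a"), c("v", "b"),
                 c("s3", "c"), c("c", "d"), c("d", "e"), c("e", "f"),
                 c("f", "g"), c("g", "a"))
  net <- interactionNetwork(as.data.frame(edges))
  expect_equal(igraph::vcount(networkGraph(net)), 11)
  hn <- hiddenNodes(net, seeds = c("s1", "s2", "s3"))
  row <- hn[hn$node == "v", ]
  expect_equal(row$degree, 4L)
  expect_equal(row$seedNeighbors, 2L)
  expect_equal(row$pvalue, 1 / 3, tolerance = 1e-12)
  # zero seed neighbors -> p = 1, never retained
  expect_true(all(hn$pvalue[hn$seedNeighbors == 0] == 1))
  expect_false(any(hn$retained[hn$seedNeighbors == 0]))
  expect_error(hiddenNodes(net, seeds = "nope"), "empty overlap")
})

test_that("hidden-nodes matches brute-force enumeration on small graphs", {
  for (s in 1:12) {
    g <- randomConnectedGraph(n = sample(6:12, 1), pEdge = 0.4,
                              seed = 700 + s)
    nodes <- igraph::V(g)$name
    seeds <- withr::with_seed(s, sample(nodes, sample(2:4, 1)))
    hn <- hiddenNodes(g, seeds)
    N <- length(nodes) - 1
    K <- length(seeds)
    for (i in seq_len(nrow(hn))) {
      expect_equal(hn$pvalue[i],
                   bruteHyperTail(hn$seedNeighbors[i], K, N, hn$degree[i]),
                   tolerance = 1e-12)
    }
    # BH never dips below the raw p-value
    expect_true(all(hn$padj >= hn$pvalue - 1e-15))
    expect_true(all(hn$score >= 0))
  }
})

test_that("hypergeometric tail is monotone: full seed overlap is extremal", {
  # among equal-degree candidates, more seed neighbors => smaller p
  N <- 10; K <- 3
  for (k in 2:4) {
    p <- vapply(0:k, function(x) bruteHyperTail(x, K, N, k), numeric(1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("propagation hits its closed forms and conserves mass", {
  g <- namedGraph(igraph::make_graph(~ a - b))
  np <- networkPropagation(g, seeds = igraph::V(g)$name[1], restart = 0.5,
                           nPerm = 20, seed = 1, tol = 1e-12)
  flow <- attr(np, "flowAll")
  expect_equal(unname(flow), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(sum(flow), 1, tolerance = 1e-12)
  # restart = 1 returns the seed distribution exactly
  np1 <- networkPropagation(g, seeds = igraph::V(g)$name[1], restart = 1,
                            nPerm = 5, seed = 1)
  expect_equal(unname(attr(np1, "flowAll")), c(1, 0))
  expect_error(networkPropagation(g, igraph::V(g)$name[1], restart = 0),
               "restart")
})

test_that("propagation equals the direct linear solve on small networks", {
  for (s in 1:5) {
    n <- sample(20:50, 1)
    g <- randomConnectedGraph(n, 0.12, seed = 800 + s)
    seeds <- withr::with_seed(s, sample(igraph::V(g)$name, 4))
    np <- networkPropagation(g, seeds, restart = 0.5, nPerm = 5,
                             seed = 1, tol = 1e-12)
    direct <- solveRWR(g, seeds, 0.5)
    expect_lt(max(abs(attr(np, "flowAll") - direct[names(attr(np,
                                                              "flowAll"))])),
              1e-8)
    expect_equal(sum(attr(np, "flowAll")), 1, tolerance = 1e-10)
  }
})

test_that("propagation p-values respect the permutation floor and BH order", {
  g <- randomConnectedGraph(40, 0.15, seed = 900)
  np <- networkPropagation(g, igraph::V(g)$name[1:4], nPerm = 50,
                           seed = 2)
  expect_true(all(np$pvalue >= 1 / 51 - 1e-15))
  expect_true(all(np$padj >= np$pvalue - 1e-15))
  # retained set is the top ceiling(frac * scored) by score
  expect_equal(sum(np$retained), ceiling(0.01 * nrow(np)))
})

test_that("robustness is exact on complete graphs", {
  k20 <- namedGraph(igraph::make_full_graph(20))
  rb <- robustness(k20, reps = 4, seed = 1)
  # floor(f * 20) removals leave a complete graph: ratios exactly 1 - f
  expect_equal(rb$curve$meanLCCRatio, 1 - rb$curve$fraction,
               tolerance = 1e-12)
  expect_equal(rb$score, 0.725, tolerance = 1e-12)
  expect_true(all(diff(rb$curve$meanLCCRatio) < 0))
  # K10, f = 0.5: every rep removes 5 of 10 -> ratio exactly 0.5
  k10 <- namedGraph(igraph::make_full_graph(10))
  rb10 <- robustness(k10, fractions = 0.5, reps = 6, seed = 2)
  expect_equal(rb10$curve$meanLCCRatio, 0.5, tolerance = 1e-12)
  expect_error(robustness(k10, fractions = 1.2), "fraction")
})

test_that("robustness of a disconnected graph is measured against the LCC", {
  big <- igraph::make_full_graph(60)
  small <- igraph::make_ring(10)
  g <- namedGraph(igraph::disjoint_union(big, small))
  rb <- robustness(g, fractions = 0.01, reps = 20, seed = 3)
  expect_gt(rb$curve$meanLCCRatio[1], 0.95)   # tends to 1 as f -> 0
  expect_lte(rb$curve$meanLCCRatio[1], 1)
})

test_that("global efficiency and criticality match the 3-path arithmetic", {
  p3 <- namedGraph(igraph::make_graph(~ x - y, y - z), "p")
  g <- igraph::make_graph(~ a - b, b - c)
  expect_equal(globalEfficiency(g), 5 / 6)
  crit <- nodeCriticality(g)
  expect_equal(unname(crit["b"]), 1)          # center disconnects
  expect_equal(unname(crit["a"]), -0.2)       # leaf removal helps
  expect_equal(unname(crit["c"]), -0.2)
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_error(nodeCriticality(empty), "zero efficiency")
})

test_that("structural metrics hit their closed-form graph examples", {
  star <- namedGraph(igraph::make_star(5, "undirected"))
  sm <- structuralMetrics(star)
  expect_equal(sm$degreeCentralization, 1)
  expect_equal(sm$betweennessCentralization, 1)
  ring <- namedGraph(igraph::make_ring(6))
  expect_equal(structuralMetrics(ring)$degreeCentralization, 0)
  twins <- namedGraph(igraph::disjoint_union(igraph::make_full_graph(3),
                                             igraph::make_full_graph(3)))
  smt <- structuralMetrics(twins)
  expect_equal(smt$modularity, 0.5)
  expect_equal(max(smt$communities), 2)
  expect_equal(smt$clustering, 1)
})

test_that("centralizations agree with igraph's Freeman formulas", {
  for (s in 1:5) {
    g <- randomConnectedGraph(25, 0.2, seed = 950 + s)
    sm <- structuralMetrics(g)
    expect_equal(sm$degreeCentralization,
                 igraph::centr_degree(g, loops = FALSE)$centralization,
                 tolerance = 1e-12)
    expect_equal(sm$betweennessCentralization,
                 igraph::centr_betw(g)$centralization, tolerance = 1e-10)
  }
})

test_that("regulator statistics follow degree arithmetic", {
  star <- namedGraph(igraph::make_star(5, "undirected"))
  rs <- regulatorStats(star, regulators = "v01")   # the hub
  expect_equal(rs$degreeRatio, 4)
  expect_equal(rs$regulatorMeanBetweenness, 1)
  expect_equal(rs$nonRegulatorMeanBetweenness, 0)
  # any split of a regular graph has ratio 1
  ring <- namedGraph(igraph::make_ring(8))
  expect_equal(regulatorStats(ring, paste0("v0", 1:3))$degreeRatio, 1)
  expect_error(regulatorStats(ring, character()), "nonempty")
})

test_that("edge-list reader handles STRING-style headers and thresholds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t0.9", "B\tC\t0.5", "C\tA\t0.2"), path)
  net <- readEdgeList(path)
  expect_equal(igraph::ecount(networkGraph(net)), 3)
  net2 <- readEdgeList(path, scoreThreshold = 0.4)
  expect_equal(igraph::ecount(networkGraph(net2)), 2)
  # headerless numeric file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t1", "B\tC\t2"), path2)
  expect_equal(igraph::ecount(networkGraph(readEdgeList(path2))), 2)
  # write/read round trip preserves the edge set
  out <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(net, out)
  back <- readEdgeList(out)
  expect_equal(igraph::ecount(networkGraph(back)), 3)
})

test_that("stability report bundles all four pillars reproducibly", {
  net <- genNetwork(netSimConfig(nNodes = 80, nRegulators = 8, seed = 5),
                    signatureNodes = sprintf("g%02d", 1:10))
  r1 <- stabilityReport(net, reps = 5, seed = 7)
  r2 <- stabilityReport(net, reps = 5, seed = 7)
  expect_equal(r1$robustness$curve, r2$robustness$curve)
  expect_equal(r1$criticality, r2$criticality)
  expect_true(r1$structural$modularity >= -0.5 &&
                r1$structural$modularity <= 1)
  expect_true(all(r1$robustness$curve$meanLCCRatio >= 0 &
                    r1$robustness$curve$meanLCCRatio <= 1))
  expect_gt(r1$regulator$degreeRatio, 1)
  path <- withr::local_tempfile(fileext = ".json")
  writeStabilityJSON(r1, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$robustnessScore, r1$robustness$score)
})
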