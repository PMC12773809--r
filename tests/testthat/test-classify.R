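test_that("stratified split reproduces the cohort arithmetic", {
  labels <- rep(c("case", "control"), c(213, 92))
  plan <- stratifiedSplit(labels, testFrac = 0.2, seed = 1)
  expect_length(plan$train, 244)
  expect_length(plan$test, 61)
  expect_setequal(c(plan$train, plan$test), seq_len(305))
  # determinism
  plan2 <- stratifiedSplit(labels, testFrac = 0.2, seed = 1)
  expect_identical(plan$test, plan2$test)
  # 5/5 cohort: one test sample per class
  p10 <- stratifiedSplit(rep(c("a", "b"), each = 5), 0.2, seed = 2)
  expect_length(p10$test, 2)
  expect_equal(as.integer(table(rep(c("a", "b"), each = 5)[p10$test])),
               c(1L, 1L))
  expect_error(stratifiedSplit(labels, testFrac = 1.2), "testFrac")
})

test_that("per-class test allocation stays within one sample of global", {
  for (s in 1:5) {
    tab <- withr::with_seed(s, sample(5:60, 3))
    y <- rep(c("a", "b", "c"), tab)
    plan <- stratifiedSplit(y, testFrac = 0.25, seed = s)
    expect_length(plan$test, round(sum(tab) * 0.25))
    for (cl in c("a", "b", "c")) {
      got <- sum(y[plan$test] == cl)
      expect_lte(abs(got - sum(y == cl) * 0.25), 1)
    }
  }
})

test_that("rank AUC is exact, tie-aware and transform-invariant", {
  y <- c("case", "case", "control", "control")
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), y), 1)
  expect_equal(aucRank(c(0.1, 0.2, 0.8, 0.9), y), 0)
  expect_equal(aucRank(c(0.5, 0.5, 0.5, 0.5), y), 0.5)   # all tied
  s <- c(0.1, 0.7, 0.4, 0.9, 0.3, 0.6)
  y2 <- c("case", "case", "control", "case", "control", "control")
  base <- aucRank(s, y2)
  expect_equal(aucRank(exp(5 * s), y2), base)     # monotone transform
  expect_equal(aucRank(rank(s), y2), base)
  expect_error(aucRank(s, rep("case", 6)), "both classes")
})

test_that("confusion-derived metrics match the worked example", {
  # TP 9, FN 1, FP 2, TN 8
  y <- rep(c("case", "control"), each = 10)
  prob <- c(rep(0.9, 9), 0.1, rep(0.9, 2), rep(0.1, 8))
  cm <- topomics:::confusionMetrics(factor(y), prob, "case", 0.5)
  expect_equal(unname(cm["sensitivity"]), 0.9)
  expect_equal(unname(cm["specificity"]), 0.8)
  expect_equal(unname(cm["f1"]), 18 / 21)
  expect_equal(unname(cm["accuracy"]), 17 / 20)
  expect_equal(unname(cm[c("tp", "fn", "fp", "tn")]), c(9, 1, 2, 8))
})

test_that("grid search returns bookkeeping-complete tables and wins on
           separable data", {
  fx <- makeSignalMatrix(n = 50, p = 5, nSig = 1, delta = 6, seed = 12)
  grid <- data.frame(nTrees = c(30L, 60L), maxDepth = 2L,
                     learningRate = 0.3, subsample = 1.0)
  gs <- gridSearchGbt(fx$X, fx$y, paramGrid = grid, k = 5, seed = 1)
  expect_equal(nrow(gs$cvTable), 2)
  expect_true(all(c("meanAUC", "sdAUC") %in% colnames(gs$cvTable)))
  expect_gte(gs$bestAUC, 0.99)
  # singleton grid returns itself
  g1 <- gridSearchGbt(fx$X, fx$y, paramGrid = grid[1, ], k = 5, seed = 1)
  expect_equal(g1$best$nTrees, 30L)
  # tie-break prefers fewer trees then shallower depth
  tied <- data.frame(nTrees = c(300L, 100L), maxDepth = c(4L, 2L),
                     learningRate = 0.3, subsample = 1.0)
  gt <- gridSearchGbt(fx$X, fx$y, paramGrid = tied, k = 5, seed = 1)
  if (abs(diff(gt$cvTable$meanAUC)) < 1e-12)
    expect_equal(gt$best$nTrees, 100L)
})

test_that("fit/evaluate reports perfect metrics with zero-width CIs on a
           separable problem", {
  withr::with_seed(13, {
    y <- factor(rep(c("case", "control"), each = 30))
    X <- cbind(f1 = as.numeric(y == "case") * 4 + rnorm(60, 0, 0.05),
               f2 = rnorm(60))
  })
  tr <- c(1:20, 31:50)
  te <- setdiff(1:60, tr)
  rep_ <- fitEval(X[tr, ], y[tr], X[te, ], y[te],
                  list(nTrees = 60L, maxDepth = 2L, learningRate = 0.3,
                       subsample = 1.0), bootB = 300, seed = 1)
  for (m in names(rep_$metrics)) {
    expect_equal(rep_$metrics[[m]]$estimate, 1)
    expect_equal(rep_$metrics[[m]]$lower, 1)
    expect_equal(rep_$metrics[[m]]$upper, 1)
  }
  expect_error(fitEval(X[tr, ], y[tr], X[te, ], rep("case", 10),
                       list(nTrees = 10L, maxDepth = 2L,
                            learningRate = 0.3, subsample = 1.0)),
               "single class")
})

test_that("bootstrap CIs contain the point estimate and stabilize with B", {
  fx <- makeSignalMatrix(n = 90, p = 10, nSig = 2, delta = 1, seed = 14)
  tr <- 1:60
  te <- 61:90
  params <- list(nTrees = 40L, maxDepth = 2L, learningRate = 0.2,
                 subsample = 1.0)
  lowers <- sapply(c(60L, 1500L), function(B) {
    vapply(1:6, function(s) {
      r <- fitEval(fx$X[tr, ], fx$y[tr], fx$X[te, ], fx$y[te], params,
                   bootB = B, seed = s)
      expect_lte(r$metrics$auc$lower, r$metrics$auc$estimate)
      expect_gte(r$metrics$auc$upper, r$metrics$auc$estimate)
      r$metrics$auc$lower
    }, numeric(1))
  })
  # endpoint jitter shrinks as B grows (point estimate fixed across seeds)
  expect_lt(sd(lowers[, 2]), sd(lowers[, 1]) + 1e-9)
})

test_that("model input assembly obeys inclusion-exclusion", {
  n <- 12
  mk <- function(p, prefix) {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("%s%02d", prefix, 1:p)))
    m
  }
  blocks <- withr::with_seed(15, list(methylation = mk(6, "cg"),
                                      expression = mk(8, "gene"),
                                      proteomics = mk(5, "prot")))
  signature <- list(methylation = c("cg01", "cg02"),
                    expression = c("gene01", "gene02", "gene03"),
                    proteomics = "prot01")
  # disjoint regulators: |MO-TR| = |MO| + |TR|
  inp <- buildModelInputs(signature, c("gene05", "gene06"), blocks)
  expect_equal(ncol(inp$MO), 6)
  expect_equal(ncol(inp$TR), 2)
  expect_equal(ncol(inp$MOTR), 8)
  # absorbed regulators: MO-TR = MO
  inp2 <- buildModelInputs(signature, c("gene01", "gene02"), blocks)
  expect_equal(sort(colnames(inp2$MOTR)), sort(colnames(inp2$MO)))
  # partial overlap: brute-force union size
  regs <- c("gene03", "gene05")
  inp3 <- buildModelInputs(signature, regs, blocks)
  expect_equal(ncol(inp3$MOTR),
               length(union(colnames(inp3$MO), regs)))
  # unresolvable IDs are reported then dropped; all-unresolvable errors
  inp4 <- buildModelInputs(signature, c("gene01", "ghost"), blocks)
  expect_equal(inp4$unresolved, "ghost")
  expect_error(buildModelInputs(signature, "ghost", blocks),
               "no regulator IDs")
})

test_that("external validation intersects features and inventories losses", {
  fx <- makeSignalMatrix(n = 80, p = 20, nSig = 4, delta = 2, seed = 16)
  hidden <- withr::with_seed(17, sample(colnames(fx$X), 10))
  extX <- fx$X[41:80, setdiff(colnames(fx$X), hidden)]
  inter <- featureIntersection(colnames(fx$X), colnames(extX))
  expect_setequal(inter$lost, hidden)          # exactly the hidden ones
  expect_equal(unname(inter$inventory), 10L)
  fb <- setNames(rep(c("meth", "expr"), each = 10), colnames(fx$X))
  inter2 <- featureIntersection(colnames(fx$X), colnames(extX), fb)
  expect_equal(sum(inter2$inventory), length(inter2$kept))
  ev <- externalValidate(colnames(fx$X), fx$X[1:40, ], fx$y[1:40],
                         extX, fx$y[41:80],
                         list(nTrees = 40L, maxDepth = 2L,
                              learningRate = 0.2, subsample = 1.0),
                         featureBlocks = fb, bootB = 100, seed = 1)
  expect_s3_class(ev$report, "MetricsReport")
  expect_equal(sum(ev$intersection$inventory), 10)
  expect_error(externalValidate(colnames(fx$X), fx$X[1:40, ], fx$y[1:40],
                                extX[, 0], fx$y[41:80],
                                list(nTrees = 10L, maxDepth = 2L,
                                     learningRate = 0.2, subsample = 1.0)),
               "empty feature intersection")
})

test_that("no training artifact depends on test rows", {
  fx <- makeSignalMatrix(n = 60, p = 8, nSig = 2, seed = 18)
  plan <- stratifiedSplit(fx$y, 0.2, seed = 3)
  poisoned <- fx$X
  poisoned[plan$test, ] <- 1e6                 # sentinel values
  runOnce <- function(X) {
    scaler <- zscoreFit(X[plan$train, ])
    Z <- zscoreApply(scaler, X)
    gs <- gridSearchGbt(Z[plan$train, ], fx$y[plan$train],
                        paramGrid = data.frame(nTrees = 20L, maxDepth = 2L,
                                               learningRate = 0.3,
                                               subsample = 1.0),
                        k = 3, seed = 4)
    model <- gbtFit(Z[plan$train, ], fx$y[plan$train], gs$best, seed = 5)
    list(scaler = scaler, cv = gs$cvTable,
         trainPred = gbtPredict(model, Z[plan$train, ]))
  }
  clean <- runOnce(fx$X)
  dirty <- runOnce(poisoned)
  expect_identical(clean$scaler, dirty$scaler)
  expect_identical(clean$cv, dirty$cv)
  expect_identical(clean$trainPred, dirty$trainPred)
})
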