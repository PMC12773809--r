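test_that("dense component 1 equals the SVD of the cross-covariance", {
  fx <- makeSignalMatrix(n = 50, p = 30, nSig = 4, seed = 21)
  fit <- splsdaFit(fx$X, fx$y, ncomp = 1, keepX = ncol(fx$X))
  Xc <- scale(fx$X, scale = FALSE)
  Y <- scale(oneHot <- sapply(sort(levels(fx$y)), function(cl)
    as.numeric(fx$y == cl)), scale = FALSE)
  u <- svd(crossprod(Xc, Y))$u[, 1]
  if (u[which.max(abs(u))] < 0) u <- -u
  expect_lt(max(abs(u - loadings(fit)[, 1])), 1e-8)
})

test_that("sparsity budget selects the dominant-covariance feature", {
  withr::with_seed(2, {
    y <- rep(c("case", "control"), each = 15)
    X <- cbind(sig = as.numeric(y == "case") + rnorm(30, 0, 0.01),
               noise = rnorm(30))
  })
  fit <- splsdaFit(X, y, ncomp = 1, keepX = 1)
  expect_equal(which(loadings(fit)[, 1] != 0), c(sig = 1L))
  # perfectly separated toy predicts its own training data exactly
  pr <- splsdaPredict(fit, X)
  expect_equal(as.character(pr$class), y)
})

test_that("model invariants hold: unit norm, exact sparsity, orthogonal
           scores, non-decreasing objective", {
  fx <- makeSignalMatrix(n = 60, p = 50, nSig = 6, seed = 31)
  keepX <- c(5L, 12L, 30L)
  fit <- splsdaFit(fx$X, fx$y, ncomp = 3, keepX = keepX)
  U <- loadings(fit)
  expect_equal(unname(sqrt(colSums(U^2))), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(colSums(U != 0)), as.integer(keepX))
  Tm <- scores(fit)
  for (h in 1:2) for (l in (h + 1):3)
    expect_lt(abs(crossprod(Tm[, h], Tm[, l])) /
                (sqrt(sum(Tm[, h]^2)) * sqrt(sum(Tm[, l]^2))), 1e-6)
  for (tr in fit@objective)
    expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))))
})

test_that("single block + outcome reduces exactly to sPLS-DA", {
  fx <- makeSignalMatrix(n = 40, p = 25, nSig = 5, seed = 41)
  s <- splsdaFit(fx$X, fx$y, ncomp = 2, keepX = c(6, 10))
  d <- diabloFit(list(b = fx$X), fx$y, ncomp = 2,
                 keepX = list(b = c(6, 10)))
  expect_lt(max(abs(loadings(s) - loadings(d)$b)), 1e-8)
  expect_lt(max(abs(scores(s) - scores(d)$b)), 1e-8)
})

test_that("zero block-block design decouples the first component", {
  fx1 <- makeSignalMatrix(n = 50, p = 20, nSig = 4, seed = 51)
  fx2 <- makeSignalMatrix(n = 50, p = 24, nSig = 4, seed = 52)
  design <- matrix(0, 2, 2)
  d <- diabloFit(list(a = fx1$X, b = fx2$X), fx1$y, ncomp = 1,
                 keepX = list(a = 6, b = 6), design = design)
  sa <- splsdaFit(fx1$X, fx1$y, ncomp = 1, keepX = 6)
  sb <- splsdaFit(fx2$X, fx1$y, ncomp = 1, keepX = 6)
  expect_lt(max(abs(loadings(d)$a[, 1] - loadings(sa)[, 1])), 1e-8)
  expect_lt(max(abs(loadings(d)$b[, 1] - loadings(sb)[, 1])), 1e-8)
})

test_that("stronger design coupling raises cross-block score correlation", {
  cors <- sapply(1:20, function(s) {
    d <- genMultiOmics(smallSimConfig(nSamples = 50, seed = s,
                                      interBlockCor = 0.5))
    blocks <- list(meth = t(assayMatrix(d, "methylation")),
                   prot = t(assayMatrix(d, "proteomics")))
    vapply(c(0, 0.1, 1), function(cc) {
      fit <- diabloFit(blocks, classLabels(d), ncomp = 1,
                       keepX = list(meth = 8, prot = 8),
                       design = matrix(cc, 2, 2))
      abs(cor(scores(fit)$meth[, 1], scores(fit)$prot[, 1]))
    }, numeric(1))
  })
  med <- apply(cors, 1, median)   # rows: c = 0, 0.1, 1
  expect_true(med[3] >= med[1])
  expect_gt(med[3], med[1] - 1e-8)
  expect_true(all(diff(med) >= -0.02))  # monotone up to simulation noise
})

test_that("multiblock prediction schemes combine block votes correctly", {
  # block 'clean' carries all the signal, 'noise' none: schemes agree
  withr::with_seed(6, {
    y <- rep(c("case", "control"), each = 20)
    clean <- cbind(s1 = as.numeric(y == "case") * 2 + rnorm(40, 0, 0.05),
                   s2 = rnorm(40, 0, 0.05))
    noise <- matrix(rnorm(40 * 6, 0, 0.01), 40, 6,
                    dimnames = list(NULL, paste0("n", 1:6)))
  })
  fit <- diabloFit(list(clean = clean, noise = noise), y, ncomp = 1,
                   keepX = list(clean = 1, noise = 2))
  pa <- diabloPredict(fit, list(clean = clean, noise = noise), "average")
  pm <- diabloPredict(fit, list(clean = clean, noise = noise),
                      "majority_vote")
  expect_equal(as.character(pa$class), y)
  # unanimity: when every block agrees the combined call matches each block
  blockCalls <- lapply(pa$blockScores, function(S)
    colnames(S)[max.col(S, ties.method = "first")])
  agree <- blockCalls$clean == blockCalls$noise
  expect_equal(as.character(pm$class)[agree], blockCalls$clean[agree])
  # missing block is an error
  expect_error(diabloPredict(fit, list(clean = clean)), "missing block")
})

test_that("average scheme follows the larger margin on 2-block conflicts", {
  classes <- c("case", "control")
  # synthetic per-block score matrices via a hand-built 2-block conflict:
  # block A mildly favors control, block B strongly favors case
  sA <- matrix(c(0.4, 0.6), 1, dimnames = list(NULL, classes))
  sB <- matrix(c(0.9, 0.1), 1, dimnames = list(NULL, classes))
  avg <- (sA + sB) / 2
  expect_equal(classes[which.max(avg)], "case")
})

test_that("signature extraction follows keepX set algebra", {
  fx <- makeSignalMatrix(n = 80, p = 100, nSig = 10, seed = 61)
  fit <- splsdaFit(fx$X, fx$y, ncomp = 2, keepX = c(8, 50))
  sig <- selectFeatures(fit)
  expect_lte(length(sig$features$block), 58)   # union bound 8 + 50
  expect_gte(length(sig$features$block), 50)
  expect_false(anyDuplicated(sig$features$block) > 0)
  # empty model -> empty signature
  sig0 <- selectFeatures(splsdaFit(fx$X, fx$y, ncomp = 0))
  expect_length(sig0$features$block, 0)
  # full-overlap bound: keepX (8, 8) can never exceed 16
  fit2 <- splsdaFit(fx$X, fx$y, ncomp = 2, keepX = c(8, 8))
  expect_lte(length(selectFeatures(fit2)$features$block), 16)
})

test_that("fit rejects invalid inputs", {
  fx <- makeSignalMatrix(n = 20, p = 10, seed = 71)
  expect_error(splsdaFit(fx$X, rep("case", 20), ncomp = 1), "two classes")
  expect_error(splsdaFit(fx$X, fx$y, ncomp = 50), "rank bound")
  expect_error(splsdaFit(fx$X, fx$y, ncomp = 1, keepX = 99), "keepX")
  expect_error(diabloFit(list(a = fx$X, b = fx$X[1:10, ]), fx$y, 1),
               "aligned")
  expect_error(diabloFit(list(a = fx$X), fx$y, 1,
                         design = matrix(c(0, 1, 0.2, 0), 2, 2)),
               "symmetric")
})

test_that("models serialize to JSON and back without changing predictions", {
  fx <- makeSignalMatrix(n = 40, p = 30, nSig = 5, seed = 81)
  path <- withr::local_tempfile(fileext = ".json")
  s <- splsdaFit(fx$X, fx$y, ncomp = 2, keepX = c(5, 7))
  writeModelJSON(s, path)
  s2 <- readModelJSON(path)
  expect_equal(splsdaPredict(s2, fx$X)$scores,
               splsdaPredict(s, fx$X)$scores, tolerance = 1e-12)
  d <- diabloFit(list(a = fx$X[, 1:15], b = fx$X[, 16:30]), fx$y,
                 ncomp = 2, keepX = list(a = c(3, 3), b = c(4, 4)))
  writeModelJSON(d, path)
  d2 <- readModelJSON(path)
  newdata <- list(a = fx$X[, 1:15], b = fx$X[, 16:30])
  expect_equal(diabloPredict(d2, newdata)$scores,
               diabloPredict(d, newdata)$scores, tolerance = 1e-12)
})
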