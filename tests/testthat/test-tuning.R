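test_that("balanced error rate is the mean of per-class error fractions", {
  expect_equal(ber(c("a", "a", "b"), c("a", "a", "b")), 0)
  # class errors 0.1 and 0.3 -> 0.2
  yt <- rep(c("a", "b"), each = 10)
  yp <- yt
  yp[1] <- "b"                      # 1/10 errors in class a
  yp[11:13] <- "a"                  # 3/10 errors in class b
  expect_equal(ber(yt, yp), 0.2)
  # majority-class predictor on a 70/30 problem scores 0.5
  yt2 <- rep(c("maj", "min"), c(70, 30))
  expect_equal(ber(yt2, rep("maj", 100)), 0.5)
  # invariance to relabeling and to duplication
  relab <- c(a = "x", b = "y")
  expect_equal(ber(relab[yt], relab[yp]), ber(yt, yp))
  expect_equal(ber(rep(yt, 3), rep(yp, 3)), ber(yt, yp))
  expect_error(ber(yt, yp, classes = c("a", "b", "c")), "absent")
})

test_that("stratified folds preserve class proportions within one sample", {
  y <- factor(rep(c("case", "control"), c(33, 17)))
  fold <- stratifiedFolds(y, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    tab <- table(y[fold == f])
    expect_lte(abs(tab[["case"]] - 33 / 5), 1)
    expect_lte(abs(tab[["control"]] - 17 / 5), 1)
  }
  expect_error(stratifiedFolds(factor(rep(c("a", "b"), c(30, 3))), k = 5),
               "fewer than k")
})

test_that("cross-validated BER is zero for an oracle and ~0.5 under label
           permutation", {
  # oracle: the first column encodes the label, predictor reads it back
  y <- factor(rep(c("case", "control"), each = 25))
  X <- cbind(lab = as.numeric(y == "case"), matrix(rnorm(100), 50, 2))
  cvo <- cvBer(function(d, yy) NULL,
               function(fit, d) ifelse(d[, "lab"] == 1, "case", "control"),
               X, y, k = 5, repeats = 3, seed = 1)
  expect_equal(cvo$meanBER, 0)
  expect_equal(cvo$sdBER, 0)
  expect_length(cvo$folds, 15)
  # label-permuted signal data: BER centers on 1/2
  fx <- makeSignalMatrix(n = 60, p = 30, nSig = 5, seed = 5)
  yPerm <- withr::with_seed(9, sample(fx$y))
  cvp <- cvBer(function(d, yy) splsdaFit(d, yy, ncomp = 1, keepX = 10),
               function(m, d) splsdaPredict(m, d)$class,
               fx$X, yPerm, k = 5, repeats = 8, seed = 2)
  expect_gt(cvp$meanBER, 0.38)
  expect_lt(cvp$meanBER, 0.62)
})

test_that("keepX grids match the published candidate sets", {
  gi <- keepxGrid("integrative")
  expect_length(gi, 9)
  expect_equal(min(gi), 10)
  expect_equal(max(gi), 50)
  expect_equal(gi, seq(10, 50, by = 5))
  gs <- keepxGrid("single")
  expect_equal(min(gs), 3)
  expect_equal(max(gs), 300)
  expect_true(all(c(3, 30, 36, 60, 75, 150, 180, 300) %in% gs))
  expect_equal(diff(gs[gs <= 30]), rep(3, 9))
  expect_equal(diff(gs[gs >= 150]), rep(30, 5))
})

test_that("component count selection follows the one-SE rule", {
  fx <- makeSignalMatrix(n = 40, p = 15, nSig = 3, seed = 6)
  expect_equal(tuneNcomp(fx$X, fx$y, maxComp = 1, k = 5, repeats = 2,
                         seed = 1)$ncomp, 1L)
  # pure noise collapses to the smallest model in most seeds
  picks <- vapply(1:20, function(s) {
    nz <- makeSignalMatrix(n = 60, p = 15, nSig = 0, seed = 100 + s)
    tuneNcomp(nz$X, nz$y, maxComp = 3, k = 5, repeats = 4,
              seed = s)$ncomp
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.8)
})

test_that("component count recovery finds the planted dimensionality", {
  # two discriminative directions require a 3-class construction: for two
  # classes the centered indicator has rank 1 and H = 1 is Bayes-optimal,
  # so dimensionality recovery is only identifiable with >= 3 classes
  picks <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      y <- factor(rep(c("a", "b", "c"), each = 20))
      X <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(NULL, sprintf("f%02d", 1:30)))
      X[y == "b", 1:5] <- X[y == "b", 1:5] + 2      # direction 1
      X[y == "c", 6:10] <- X[y == "c", 6:10] + 2    # direction 2
    })
    tuneNcomp(X, y, maxComp = 4, k = 5, repeats = 2, seed = s)$ncomp
  }, integer(1))
  expect_gte(mean(picks %in% c(2L, 3L)), 0.8)
  expect_gte(mean(picks >= 2L), 0.8)   # never collapses below the truth
})

test_that("greedy keepX tuning recovers the planted sparsity level", {
  tk0 <- tuneKeepx(makeSignalMatrix(seed = 7)$X,
                   makeSignalMatrix(seed = 7)$y, ncomp = 2, grid = 10,
                   k = 5, repeats = 1, seed = 1)
  expect_equal(tk0$keepX, c(10L, 10L))          # singleton grid
  expect_equal(nrow(tk0$surface), 2)            # |grid| x ncomp rows
  picks <- vapply(1:20, function(s) {
    fx <- makeSignalMatrix(n = 80, p = 100, nSig = 15, delta = 1.2,
                           seed = 500 + s)
    tuneKeepx(fx$X, fx$y, ncomp = 1, grid = seq(10, 50, 5), k = 5,
              repeats = 1, seed = s)$keepX[1]
  }, numeric(1))
  expect_gte(mean(picks %in% c(10, 15, 20)), 0.7)
})

test_that("keepX tuning reports the full BER surface for multiblock data", {
  d <- genMultiOmics(smallSimConfig(nSamples = 40, seed = 8))
  blocks <- list(meth = t(assayMatrix(d, "methylation")),
                 prot = t(assayMatrix(d, "proteomics")))
  tk <- tuneKeepx(blocks, classLabels(d), ncomp = 1, grid = c(5, 10),
                  k = 4, repeats = 1, seed = 2)
  expect_named(tk$keepX, c("meth", "prot"))
  expect_equal(nrow(tk$surface), 2 * 2)         # |grid| x blocks x ncomp
  expect_true(all(tk$surface$meanBER >= 0 & tk$surface$meanBER <= 1))
})

test_that("bootstrap stability frequencies are exact bookkeeping", {
  fx <- makeSignalMatrix(n = 40, p = 20, nSig = 2, delta = 3, seed = 9)
  b1 <- bootstrapStability(fx$X, fx$y, ncomp = 1, keepX = 4, B = 1,
                           seed = 1)
  expect_true(all(b1$frequency %in% c(0, 1)))
  bs <- bootstrapStability(fx$X, fx$y, ncomp = 1, keepX = 4, B = 25,
                           seed = 1)
  # sum property: total frequency mass = selections per fit x fits
  expect_equal(sum(bs$frequency) * 25 / 25, 4)  # keepX selected each fit
  expect_true(all(bs$frequency >= 0 & bs$frequency <= 1))
})

test_that("stability separates overwhelming signal from exchangeable noise", {
  # one overwhelming feature at delta = 3
  fx <- makeSignalMatrix(n = 60, p = 40, nSig = 1, delta = 3, seed = 10)
  bs <- bootstrapStability(fx$X, fx$y, ncomp = 1, keepX = 3, B = 200,
                           seed = 3)
  expect_gte(bs$frequency[bs$feature == "f001"], 0.95)
  # pure-noise features: average frequency ~ keepX / p
  nz <- makeSignalMatrix(n = 60, p = 60, nSig = 0, seed = 11)
  bn <- bootstrapStability(nz$X, nz$y, ncomp = 1, keepX = 5, B = 100,
                           seed = 4)
  expect_equal(mean(bn$frequency), 5 / 60, tolerance = 1e-12)
})
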