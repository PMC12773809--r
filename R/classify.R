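# Final supervised models on the multi-omics signature (MO), the
# topological regulators (TR) and their union (MO-TR): stratified split,
# gradient-boosted-tree grid search, held-out evaluation with bootstrap
# confidence intervals, and external validation by feature intersection.

#' Stratified train/test split with largest-remainder rounding
#'
#' Allocates round(n * testFrac) samples to the test set overall; per class
#' the allocation starts from floor(class_n * testFrac) and the remaining
#' slots go to the classes with the largest fractional remainders, so every
#' class's test fraction is within one sample of the global one.
#'
#' @param labels per-sample class labels (factor or coercible); names, if
#'   present, are carried into the plan.
#' @param testFrac test fraction in (0, 1), default 0.2.
#' @param seed RNG seed for the within-class shuffles.
#' @return A \code{SplitPlan} list: \code{train}, \code{test} (integer
#'   indices), \code{testFrac}, \code{seed}.
#' @examples
#' plan <- stratifiedSplit(rep(c("case", "control"), c(213, 92)),
#'                         testFrac = 0.2, seed = 1)
#' lengths(plan[c("train", "test")])   # 244, 61
#' @export
stratifiedSplit <- function(labels, testFrac = 0.2, seed = 1L) {
  if (testFrac <= 0 || testFrac >= 1) stop("testFrac must lie in (0, 1)")
  y <- factor(labels)
  tab <- table(y)
  if (any(tab < 2L)) stop("every class needs at least 2 members")
  n <- length(y)
  nTest <- round(n * testFrac)
  ideal <- as.numeric(tab) * testFrac
  base <- floor(ideal)
  rem <- nTest - sum(base)
  if (rem > 0) {
    extra <- order(-(ideal - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    give <- order(ideal - base)[seq_len(-rem)]
    base[give] <- base[give] - 1L
  }
  testIdx <- withSeed(seed, unlist(lapply(seq_along(levels(y)), function(ci) {
    idx <- sample(which(y == levels(y)[ci]))
    idx[seq_len(base[ci])]
  }), use.names = FALSE))
  testIdx <- sort(testIdx)
  plan <- list(train = setdiff(seq_len(n), testIdx), test = testIdx,
               testFrac = testFrac, seed = seed,
               labels = setNames(as.character(y), names(labels)))
  class(plan) <- "SplitPlan"
  plan
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat(sprintf("SplitPlan: %d train / %d test (testFrac %.2f, seed %d)\n",
              length(x$train), length(x$test), x$testFrac, x$seed))
  invisible(x)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' \code{AUC = (mean rank of positives - (n1 + 1) / 2) / n0}, with midranks
#' for ties; invariant under strictly monotone score transforms.
#'
#' @param scores numeric predicted scores.
#' @param labels true labels.
#' @param positive the positive class (default \code{"case"} if present,
#'   else the first sorted class).
#' @return AUC in [0, 1].
#' @export
aucRank <- function(scores, labels, positive = NULL) {
  y <- factor(labels)
  if (is.null(positive))
    positive <- if ("case" %in% levels(y)) "case" else sort(levels(y))[1L]
  pos <- y == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (mean(r[pos]) - (n1 + 1) / 2) / n0
}

#' Default gradient-boosted-tree hyperparameter grid
#'
#' Tree count (100, 300), depth (2, 3, 4), learning rate (0.05, 0.1),
#' subsample (0.8, 1.0): 24 candidates.
#'
#' @return data.frame with columns nTrees, maxDepth, learningRate,
#'   subsample.
#' @export
gbtDefaultGrid <- function() {
  expand.grid(nTrees = c(100L, 300L), maxDepth = c(2L, 3L, 4L),
              learningRate = c(0.05, 0.1), subsample = c(0.8, 1.0),
              KEEP.OUT.ATTRS = FALSE)
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary Newton boosting with logistic loss: each round fits a
#' depth-limited regression tree to the gradient/hessian of the current
#' margin (exact greedy splits, L2 leaf regularization lambda = 1) and adds
#' shrunken Newton leaf weights. Row subsampling draws from R's RNG, so
#' results are reproducible under the \code{seed}.
#'
#' @param X samples-by-features numeric matrix.
#' @param y labels; the positive class is \code{"case"} when present,
#'   otherwise the first sorted level.
#' @param params list/row with nTrees, maxDepth, learningRate, subsample.
#' @param seed RNG seed for subsampling.
#' @param minChild minimum samples per child node (default 5).
#' @return A \code{GbtModel} list (opaque; see \code{\link{gbtPredict}}).
#' @export
gbtFit <- function(X, y, params = list(nTrees = 100L, maxDepth = 3L,
                                       learningRate = 0.1, subsample = 1.0),
                   seed = 1L, minChild = 5L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("y must contain two classes")
  positive <- if ("case" %in% levels(y)) "case" else sort(levels(y))[1L]
  y01 <- as.integer(y == positive)
  fit <- withSeed(seed, .gbt_fit_cpp(X, y01, as.integer(params$nTrees),
                                     as.integer(params$maxDepth),
                                     as.numeric(params$learningRate),
                                     as.numeric(params$subsample), 1.0,
                                     as.integer(minChild)))
  structure(list(core = fit, positive = positive,
                 classes = sort(levels(y)), features = colnames(X),
                 params = params, seed = seed),
            class = "GbtModel")
}

#' Predict case probabilities from a GbtModel
#' @param model a \code{GbtModel}.
#' @param X samples-by-features matrix with the training features.
#' @return Numeric vector of positive-class probabilities.
#' @export
gbtPredict <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  as.numeric(.gbt_predict_cpp(model$core, X))
}

#' @export
print.GbtModel <- function(x, ...) {
  cat(sprintf("GbtModel: %d trees, depth %d, lr %.3g, subsample %.2g\n",
              x$params$nTrees, x$params$maxDepth, x$params$learningRate,
              x$params$subsample))
  invisible(x)
}

#' Grid search for gradient-boosted trees by cross-validated AUC
#'
#' Exhaustive search over the hyperparameter grid under seeded stratified
#' k-fold CV; selection by mean CV AUC with ties broken toward fewer trees,
#' then shallower depth.
#'
#' @param X training samples-by-features matrix.
#' @param y training labels.
#' @param paramGrid data.frame of candidates (default
#'   \code{\link{gbtDefaultGrid}}).
#' @param k folds (default 5).
#' @param seed RNG seed (folds and subsampling).
#' @return List with \code{best} (list of hyperparameters),
#'   \code{bestAUC}, and \code{cvTable} (grid plus meanAUC, sdAUC).
#' @export
gridSearchGbt <- function(X, y, paramGrid = gbtDefaultGrid(), k = 5L,
                          seed = 1L) {
  if (!nrow(paramGrid)) stop("paramGrid must be nonempty")
  y <- factor(y)
  fold <- stratifiedFolds(y, k = k, seed = seed)
  res <- t(vapply(seq_len(nrow(paramGrid)), function(g) {
    params <- as.list(paramGrid[g, , drop = FALSE])
    aucs <- vapply(seq_len(k), function(f) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (nlevels(droplevels(y[tr])) < 2L)
        stop("degenerate single-class fold")
      m <- gbtFit(X[tr, , drop = FALSE], y[tr], params,
                  seed = seed + 1000L * f)
      aucRank(gbtPredict(m, X[te, , drop = FALSE]), y[te],
              positive = m$positive)
    }, numeric(1))
    c(mean(aucs), sd(aucs))
  }, numeric(2)))
  cvTable <- cbind(paramGrid, meanAUC = res[, 1L], sdAUC = res[, 2L])
  ord <- order(-round(cvTable$meanAUC, 12), cvTable$nTrees,
               cvTable$maxDepth)
  best <- as.list(paramGrid[ord[1L], , drop = FALSE])
  list(best = best, bestAUC = cvTable$meanAUC[ord[1L]], cvTable = cvTable)
}

confusionMetrics <- function(yTrue, prob, positive, threshold = 0.5) {
  pred <- prob >= threshold
  pos <- yTrue == positive
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(accuracy = (tp + tn) / length(yTrue), sensitivity = sens,
    specificity = spec, f1 = f1, tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Fit on training data and evaluate on held-out test data
#'
#' Fits the gradient-boosted model on the full training set, scores the
#' test set, and reports AUC (rank statistic), accuracy, sensitivity (case
#' recall), specificity (control recall) and F1 on the case class at the
#' given probability threshold, each with a 95 percent stratified
#' percentile-bootstrap confidence interval over test samples. Feature
#' scaling is the caller's job (fit the scaler on training data only; see
#' \code{\link{zscoreFit}}).
#'
#' @param Xtrain,ytrain training matrix and labels.
#' @param Xtest,ytest held-out matrix and labels (both classes required).
#' @param params gradient-boosting hyperparameters (e.g. from
#'   \code{\link{gridSearchGbt}}).
#' @param threshold probability threshold for the confusion matrix
#'   (default 0.5).
#' @param bootB bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @return A \code{MetricsReport} list: per metric a point estimate and
#'   \code{lower}/\code{upper} CI bounds, plus the confusion matrix,
#'   probabilities, \code{bootB} and \code{seed}.
#' @export
fitEval <- function(Xtrain, ytrain, Xtest, ytest, params,
                    threshold = 0.5, bootB = 2000L, seed = 1L) {
  ytest <- factor(ytest)
  model <- gbtFit(Xtrain, ytrain, params, seed = seed)
  positive <- model$positive
  if (length(unique(ytest[!is.na(ytest)])) < 2L)
    stop("AUC undefined: test set contains a single class")
  prob <- gbtPredict(model, Xtest)
  pointCM <- confusionMetrics(ytest, prob, positive, threshold)
  point <- c(auc = aucRank(prob, ytest, positive), pointCM[1:4])
  boot <- withSeed(seed, {
    idxPos <- which(ytest == positive)
    idxNeg <- which(ytest != positive)
    t(vapply(seq_len(bootB), function(b) {
      idx <- c(sample(idxPos, length(idxPos), replace = TRUE),
               sample(idxNeg, length(idxNeg), replace = TRUE))
      cm <- confusionMetrics(ytest[idx], prob[idx], positive, threshold)
      c(auc = aucRank(prob[idx], ytest[idx], positive), cm[1:4])
    }, numeric(5)))
  })
  ci <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  metrics <- lapply(names(point), function(m) {
    list(estimate = unname(point[[m]]),
         lower = min(unname(ci[1L, m]), unname(point[[m]])),
         upper = max(unname(ci[2L, m]), unname(point[[m]])))
  })
  names(metrics) <- names(point)
  rep_ <- list(metrics = metrics,
               confusion = pointCM[c("tp", "fn", "fp", "tn")],
               threshold = threshold, probabilities = prob,
               positive = positive, bootB = bootB, seed = seed,
               model = model)
  class(rep_) <- "MetricsReport"
  rep_
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (positive class:", x$positive, ")\n")
  for (m in names(x$metrics))
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m, x$metrics[[m]]$estimate,
                x$metrics[[m]]$lower, x$metrics[[m]]$upper))
  invisible(x)
}

#' Metrics table in publication shape
#'
#' One row per metric with the point estimate and 95 percent CI, matching
#' the model-by-metric layout of the package's evaluation reports.
#'
#' @param reports named list of \code{MetricsReport}s (one per model).
#' @return data.frame with model, metric, estimate, lower, upper.
#' @export
metricsTable <- function(reports) {
  do.call(rbind, lapply(names(reports), function(mn) {
    r <- reports[[mn]]
    do.call(rbind, lapply(names(r$metrics), function(m)
      data.frame(model = mn, metric = m,
                 estimate = r$metrics[[m]]$estimate,
                 lower = r$metrics[[m]]$lower,
                 upper = r$metrics[[m]]$upper, row.names = NULL)))
  }))
}

#' Assemble MO / TR / MO-TR model input tables
#'
#' MO = the per-block multi-omics signature features; TR = the expression
#' features of the topological regulator genes (unresolvable IDs are
#' reported and dropped); MO-TR = their deduplicated union.
#'
#' @param signature a \code{FeatureSignature} from
#'   \code{\link{selectFeatures}}, or a named list of per-block feature
#'   IDs.
#' @param regulators character regulator node IDs.
#' @param blocks named list of samples-by-features matrices (must include
#'   an \code{expression} block for the regulators, or give
#'   \code{regulatorBlock}).
#' @param regulatorBlock block name the regulators resolve against
#'   (default \code{"expression"}).
#' @return List with \code{MO}, \code{TR}, \code{MOTR} (samples x features
#'   matrices), \code{featureBlocks} (named vector mapping feature to
#'   block) and \code{unresolved} (dropped regulator IDs).
#' @export
buildModelInputs <- function(signature, regulators, blocks,
                             regulatorBlock = "expression") {
  sigList <- if (inherits(signature, "FeatureSignature"))
    signature$features else signature
  sigList <- sigList[intersect(names(sigList), names(blocks))]
  moCols <- list()
  featureBlocks <- character()
  for (bn in names(sigList)) {
    f <- intersect(sigList[[bn]], colnames(blocks[[bn]]))
    if (!length(f)) next
    moCols[[bn]] <- blocks[[bn]][, f, drop = FALSE]
    featureBlocks[f] <- bn
  }
  if (!length(moCols)) stop("no signature features resolve against blocks")
  MO <- do.call(cbind, unname(moCols))
  if (!regulatorBlock %in% names(blocks))
    stop("regulator block '", regulatorBlock, "' not among blocks")
  regulators <- unique(as.character(regulators))
  resolved <- intersect(regulators, colnames(blocks[[regulatorBlock]]))
  unresolved <- setdiff(regulators, resolved)
  if (!length(resolved))
    stop("no regulator IDs resolve against the ", regulatorBlock, " block")
  TR <- blocks[[regulatorBlock]][, resolved, drop = FALSE]
  featureBlocks[setdiff(resolved, names(featureBlocks))] <- regulatorBlock
  motrFeatures <- unique(c(colnames(MO), resolved))
  all <- cbind(MO, TR[, setdiff(resolved, colnames(MO)), drop = FALSE])
  MOTR <- all[, motrFeatures, drop = FALSE]
  list(MO = MO, TR = TR, MOTR = MOTR, featureBlocks = featureBlocks,
       unresolved = unresolved)
}

#' Intersect model features with an externally measured feature space
#'
#' @param features character model feature IDs.
#' @param externalFeatures character features available externally.
#' @param featureBlocks optional named vector mapping features to
#'   modalities, for the per-modality inventory.
#' @return List with \code{kept}, \code{lost}, and \code{inventory}
#'   (per-modality kept counts; total equals \code{length(kept)}).
#' @export
featureIntersection <- function(features, externalFeatures,
                                featureBlocks = NULL) {
  kept <- intersect(features, externalFeatures)
  lost <- setdiff(features, externalFeatures)
  inv <- if (is.null(featureBlocks)) c(all = length(kept))
         else table(factor(featureBlocks[kept]))
  list(kept = kept, lost = lost,
       inventory = setNames(as.integer(inv), names(inv)))
}

#' External validation on an independent cohort
#'
#' Intersects the model's features with those measured externally (exact ID
#' match), refits the classifier on the source training data restricted to
#' the intersection (scaler refit on training data only), and evaluates on
#' the external samples.
#'
#' @param features character model feature IDs.
#' @param Xtrain,ytrain source training data (samples x features,
#'   unscaled).
#' @param Xexternal,yexternal external cohort data (samples x features,
#'   unscaled; must share at least one model feature).
#' @param params gradient-boosting hyperparameters.
#' @param featureBlocks optional feature-to-modality map for the
#'   intersection inventory.
#' @param threshold,bootB,seed as in \code{\link{fitEval}}.
#' @return List with \code{report} (a \code{MetricsReport}) and
#'   \code{intersection} (from \code{\link{featureIntersection}}).
#' @export
externalValidate <- function(features, Xtrain, ytrain, Xexternal, yexternal,
                             params, featureBlocks = NULL, threshold = 0.5,
                             bootB = 2000L, seed = 1L) {
  inter <- featureIntersection(features, colnames(Xexternal), featureBlocks)
  if (!length(inter$kept))
    stop("empty feature intersection with the external data")
  Xtr <- Xtrain[, inter$kept, drop = FALSE]
  Xex <- Xexternal[, inter$kept, drop = FALSE]
  scaler <- zscoreFit(Xtr)
  rep_ <- fitEval(zscoreApply(scaler, Xtr), ytrain,
                  zscoreApply(scaler, Xex), yexternal, params,
                  threshold = threshold, bootB = bootB, seed = seed)
  list(report = rep_, intersection = inter)
}
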