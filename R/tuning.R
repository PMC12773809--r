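# Hyperparameter selection by balanced error rate under repeated stratified
# cross-validation, plus bootstrap stability of feature selection.

#' Balanced error rate
#'
#' Mean over the modeled classes (the levels present in \code{yTrue}) of
#' each class's misclassification fraction; insensitive to class imbalance.
#'
#' @param yTrue true labels (factor or character).
#' @param yPred predicted labels, same length.
#' @param classes optional vector of modeled classes; every one must occur
#'   in \code{yTrue}. Defaults to the classes present in \code{yTrue}.
#' @return BER in [0, 1].
#' @examples
#' ber(c("a", "a", "b"), c("a", "a", "b"))  # 0
#' @export
ber <- function(yTrue, yPred, classes = NULL) {
  yTrue <- factor(yTrue)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have the same length")
  cls <- levels(droplevels(yTrue))
  if (!is.null(classes)) {
    if (!all(classes %in% cls))
      stop("a modeled class is absent from yTrue")
    cls <- as.character(classes)
  }
  yPred <- as.character(yPred)
  errs <- vapply(cls, function(cl) {
    idx <- yTrue == cl
    mean(yPred[idx] != cl)
  }, numeric(1))
  mean(errs)
}

#' Stratified k-fold partition
#'
#' Assigns each sample to one of \code{k} folds so per-fold class
#' proportions deviate from the global ones by at most one sample.
#'
#' @param y class labels.
#' @param k number of folds; every class must have at least \code{k}
#'   members.
#' @param seed RNG seed for the within-class shuffles.
#' @return Integer fold assignment of length \code{length(y)}.
#' @export
stratifiedFolds <- function(y, k = 5L, seed = 1L) {
  y <- factor(y)
  tab <- table(y)
  if (any(tab < k))
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(tab)[which.min(tab)], k))
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

subsetRows <- function(data, idx) {
  if (is.list(data) && !is.data.frame(data))
    lapply(data, function(m) m[idx, , drop = FALSE])
  else data[idx, , drop = FALSE]
}

#' Cross-validated balanced error rate
#'
#' Runs \code{repeats} independent seeded stratified k-fold partitions,
#' calls \code{fitFun(trainData, trainY)} and
#' \code{predictFun(fit, testData)} per fold, and pools the per-fold BERs.
#'
#' @param fitFun function(data, y) returning a fitted object.
#' @param predictFun function(fit, data) returning predicted labels (or a
#'   list with a \code{class} element).
#' @param data samples-in-rows matrix, or list of such matrices (multiblock).
#' @param y class labels.
#' @param k folds (default 5).
#' @param repeats number of repeated partitions.
#' @param seed base seed; repeat r uses \code{seed + r - 1}.
#' @return A \code{CVResult} list: \code{meanBER}, \code{sdBER} (over all
#'   fold x repeat evaluations), \code{folds} (per-evaluation BERs),
#'   \code{k}, \code{repeats}, \code{seed}.
#' @export
cvBer <- function(fitFun, predictFun, data, y, k = 5L, repeats = 1L,
                  seed = 1L) {
  y <- factor(y)
  bers <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratifiedFolds(y, k = k, seed = seed + r - 1L)
    for (f in seq_len(k)) {
      testIdx <- which(fold == f)
      trainIdx <- which(fold != f)
      fit <- fitFun(subsetRows(data, trainIdx), y[trainIdx])
      pred <- predictFun(fit, subsetRows(data, testIdx))
      if (is.list(pred) && !is.null(pred$class)) pred <- pred$class
      bers <- c(bers, ber(y[testIdx], pred))
    }
  }
  structure(list(meanBER = mean(bers), sdBER = sd(bers), folds = bers,
                 k = k, repeats = repeats, seed = seed),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: mean BER %.4f (sd %.4f) over %d x %d folds\n",
              x$meanBER, x$sdBER, x$k, x$repeats))
  invisible(x)
}

#' Choose the number of components by a one-standard-deviation rule
#'
#' Evaluates dense models (keepX = all features) with 1..\code{maxComp}
#' components under repeated stratified CV and returns the smallest
#' component count whose mean BER is within one pooled standard deviation
#' (over all fold-by-repeat evaluations) of the global minimum.
#'
#' @param data matrix or named list of matrices (samples in rows).
#' @param y class labels.
#' @param maxComp largest component count tried (default 6).
#' @param k,repeats,seed CV control; see \code{\link{cvBer}}.
#' @param design passed to \code{\link{diabloFit}} for multiblock data.
#' @return List with \code{ncomp} (the choice) and \code{cv} (per-H
#'   \code{CVResult}s).
#' @export
tuneNcomp <- function(data, y, maxComp = 6L, k = 5L, repeats = 100L,
                      seed = 1L, design = NULL) {
  stopifnot(maxComp >= 1L)
  multiblock <- is.list(data) && !is.data.frame(data)
  cvs <- vector("list", maxComp)
  for (H in seq_len(maxComp)) {
    if (multiblock) {
      fitFun <- function(d, yy) diabloFit(d, yy, ncomp = H, design = design)
      predFun <- function(m, d) diabloPredict(m, d)$class
    } else {
      fitFun <- function(d, yy) splsdaFit(d, yy, ncomp = H)
      predFun <- function(m, d) splsdaPredict(m, d)$class
    }
    cvs[[H]] <- cvBer(fitFun, predFun, data, y, k = k, repeats = repeats,
                      seed = seed)
  }
  means <- vapply(cvs, `[[`, numeric(1), "meanBER")
  sds <- vapply(cvs, `[[`, numeric(1), "sdBER")
  best <- which.min(means)
  # smallest H within one pooled SD of the global minimum
  choice <- which(means <= means[best] + sds[best])[1L]
  list(ncomp = as.integer(choice), cv = cvs, meanBER = means)
}

#' Candidate keepX grids
#'
#' \code{single}: 3 to 300 with steps of 3 (3-30), 6 (30-60), 15 (60-150)
#' and 30 (150-300). \code{integrative}: 10 to 50 in steps of 5 (nine
#' candidate values per component per block).
#'
#' @param kind \code{"single"} or \code{"integrative"}.
#' @return Integer vector of candidate keepX values.
#' @examples
#' length(keepxGrid("integrative"))  # 9
#' @export
keepxGrid <- function(kind = c("single", "integrative")) {
  kind <- match.arg(kind)
  if (kind == "integrative") return(seq(10L, 50L, by = 5L))
  unique(c(seq(3L, 30L, by = 3L), seq(30L, 60L, by = 6L),
           seq(60L, 150L, by = 15L), seq(150L, 300L, by = 30L)))
}

#' Sequential per-component keepX tuning by CV balanced error rate
#'
#' Greedy search: with components 1..h-1 fixed at their chosen budgets,
#' every grid value is evaluated for component h under repeated stratified
#' CV and the BER minimizer is kept (ties to the smaller keepX). For
#' multiblock data the greedy loop additionally cycles over blocks within
#' each component (non-active blocks hold their current budget, initialized
#' at the grid median).
#'
#' @param data matrix or named list of matrices (samples in rows).
#' @param y class labels.
#' @param ncomp number of components to tune.
#' @param grid candidate keepX values (nonempty integer vector).
#' @param k,repeats,seed CV control.
#' @param design multiblock design matrix (optional).
#' @return List with \code{keepX} (vector, or named list per block),
#'   \code{surface} (data.frame: block, component, keepX, meanBER, sdBER).
#' @export
tuneKeepx <- function(data, y, ncomp, grid = NULL, k = 5L, repeats = 100L,
                      seed = 1L, design = NULL) {
  multiblock <- is.list(data) && !is.data.frame(data)
  if (is.null(grid)) grid <- keepxGrid(if (multiblock) "integrative"
                                       else "single")
  if (!length(grid)) stop("grid must be nonempty")
  grid <- sort(unique(as.integer(grid)))
  if (!multiblock) {
    pmax <- ncol(data)
    grid <- grid[grid <= pmax]
    chosen <- integer(0)
    surface <- NULL
    for (h in seq_len(ncomp)) {
      res <- vapply(grid, function(g) {
        kx <- c(chosen, g)
        cv <- cvBer(function(d, yy) splsdaFit(d, yy, ncomp = h, keepX = kx),
                    function(m, d) splsdaPredict(m, d)$class,
                    data, y, k = k, repeats = repeats, seed = seed)
        c(cv$meanBER, cv$sdBER)
      }, numeric(2))
      surface <- rbind(surface, data.frame(
        block = "block", component = h, keepX = grid,
        meanBER = res[1L, ], sdBER = res[2L, ]))
      chosen <- c(chosen, grid[which.min(res[1L, ])])
    }
    return(list(keepX = chosen, surface = surface))
  }
  blocks <- names(data)
  gridB <- lapply(data, function(m) grid[grid <= ncol(m)])
  current <- lapply(blocks, function(bn) integer(0))
  names(current) <- blocks
  surface <- NULL
  for (h in seq_len(ncomp)) {
    for (bn in blocks)  # initialize component h at the grid median
      current[[bn]] <- c(current[[bn]],
                         gridB[[bn]][ceiling(length(gridB[[bn]]) / 2)])
    for (bn in blocks) {
      g <- gridB[[bn]]
      res <- vapply(g, function(gv) {
        kx <- current
        kx[[bn]][h] <- gv
        cv <- cvBer(function(d, yy) diabloFit(d, yy, ncomp = h,
                                              keepX = lapply(kx, head, h),
                                              design = design),
                    function(m, d) diabloPredict(m, d)$class,
                    data, y, k = k, repeats = repeats, seed = seed)
        c(cv$meanBER, cv$sdBER)
      }, numeric(2))
      surface <- rbind(surface, data.frame(
        block = bn, component = h, keepX = g,
        meanBER = res[1L, ], sdBER = res[2L, ]))
      current[[bn]][h] <- g[which.min(res[1L, ])]
    }
  }
  list(keepX = current, surface = surface)
}

#' Bootstrap stability of feature selection
#'
#' Draws \code{B} class-stratified with-replacement resamples of the
#' samples, refits the sparse model at fixed (ncomp, keepX), and reports
#' each feature's selection frequency: the fraction of fits in which it
#' received a nonzero loading on any component.
#'
#' @param data matrix or named list of matrices (samples in rows).
#' @param y class labels.
#' @param ncomp,keepX fixed model size (keepX: vector, or list per block).
#' @param B bootstrap iterations (>= 1).
#' @param seed RNG seed.
#' @param design multiblock design (optional).
#' @return A \code{StabilityScores} data.frame: block, feature, frequency
#'   (exactly timesSelected / B), with attribute \code{B}.
#' @export
bootstrapStability <- function(data, y, ncomp, keepX, B = 1000L, seed = 1L,
                               design = NULL) {
  stopifnot(B >= 1L)
  y <- factor(y)
  multiblock <- is.list(data) && !is.data.frame(data)
  feats <- if (multiblock) lapply(data, colnames)
           else list(block = colnames(data))
  counts <- lapply(feats, function(f) setNames(integer(length(f)), f))
  withSeed(seed, {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(levels(y), function(cl) {
        w <- which(y == cl)
        sample(w, length(w), replace = TRUE)
      }), use.names = FALSE)
      fit <- if (multiblock)
        diabloFit(subsetRows(data, idx), y[idx], ncomp = ncomp,
                  keepX = keepX, design = design)
      else splsdaFit(data[idx, , drop = FALSE], y[idx], ncomp = ncomp,
                     keepX = keepX)
      sig <- selectFeatures(fit)$features
      for (bn in names(counts)) {
        hit <- names(counts[[bn]]) %in% sig[[bn]]
        counts[[bn]][hit] <- counts[[bn]][hit] + 1L
      }
    }
  })
  out <- do.call(rbind, lapply(names(counts), function(bn)
    data.frame(block = bn, feature = names(counts[[bn]]),
               frequency = as.numeric(counts[[bn]]) / B, row.names = NULL)))
  attr(out, "B") <- B
  class(out) <- c("StabilityScores", class(out))
  out
}

#' Write a tuning surface / stability table to TSV
#' @param x data.frame (tuning surface or StabilityScores).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeReportTSV <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
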