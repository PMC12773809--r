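# Sparse PLS-DA and its multiblock (DIABLO-style) extension, implemented
# from first principles: alternating least squares on the covariance
# objective with an exact-cardinality soft-threshold (keepX), regression
# deflation, and indicator-regression / centroid prediction.

oneHotIndicator <- function(y) {
  y <- factor(y)
  classes <- sort(levels(y))
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(names(y), classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

# keep the k largest |entries| (ties by input order), shrink survivors by
# the (k+1)-th largest magnitude; k >= length(u) leaves u dense.
softKeep <- function(u, k) {
  p <- length(u)
  if (k >= p) return(u)
  a <- abs(u)
  ord <- order(-a)                     # stable sort: ties keep input order
  lambda <- a[ord[k + 1L]]
  out <- numeric(p)
  keep <- ord[seq_len(k)]
  out[keep] <- sign(u[keep]) * (a[keep] - lambda)
  out
}

unitNorm <- function(u) {
  nrm <- sqrt(sum(u^2))
  if (nrm < .Machine$double.eps) stop("degenerate zero loading vector")
  u / nrm
}

signFix <- function(u) {
  i <- which.max(abs(u))
  if (u[i] < 0) -u else u
}

centerColumns <- function(X, scale = FALSE) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sc <- rep(1, ncol(X))
  if (scale) {
    sc <- apply(Xc, 2L, sd)
    sc[sc == 0 | !is.finite(sc)] <- 1
    Xc <- sweep(Xc, 2L, sc, "/")
  }
  list(X = Xc, mean = mu, scale = sc)
}

# Shared block-coordinate engine. blocks: named list of centered n x p_i
# matrices; Yc: centered indicator; design: (K+1)x(K+1) with outcome last.
# Returns per-component loadings/scores plus deflation byproducts.
multiblockEngine <- function(blocksC, Yc, ncomp, keepX, design,
                             tol = 1e-6, maxIter = 100L) {
  K <- length(blocksC)
  n <- nrow(Yc)
  cY <- design[seq_len(K), K + 1L]
  fit <- lapply(blocksC, function(X)
    list(U = matrix(0, ncol(X), 0), P = matrix(0, ncol(X), 0),
         Tm = matrix(0, n, 0)))
  V <- matrix(0, ncol(Yc), 0)
  Cl <- matrix(0, ncol(Yc), 0)
  Tbar <- matrix(0, n, 0)
  objective <- vector("list", ncomp)
  Xd <- blocksC
  Yd <- Yc
  for (h in seq_len(ncomp)) {
    u <- vector("list", K)
    tScores <- vector("list", K)
    for (i in seq_len(K)) {
      M <- crossprod(Xd[[i]], Yd)
      ui <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
      ui <- unitNorm(signFix(softKeep(ui, keepX[[i]][h])))
      u[[i]] <- ui
      tScores[[i]] <- drop(Xd[[i]] %*% ui)
    }
    v <- unitNorm(Reduce(`+`, lapply(seq_len(K), function(i)
      cY[i] * drop(crossprod(Yd, tScores[[i]])))))
    tY <- drop(Yd %*% v)
    obj <- numeric(0)
    evalObj <- function() {
      s <- 0
      if (K > 1L)
        for (i in seq_len(K - 1L)) for (j in seq.int(i + 1L, K))
          s <- s + design[i, j] * crossprod(tScores[[i]], tScores[[j]]) / (n - 1)
      for (i in seq_len(K))
        s <- s + cY[i] * crossprod(tScores[[i]], tY) / (n - 1)
      as.numeric(s)
    }
    iter <- 0L
    repeat {
      iter <- iter + 1L
      delta <- 0
      for (i in seq_len(K)) {
        z <- cY[i] * drop(crossprod(Xd[[i]], tY))
        if (K > 1L) for (j in seq_len(K)) if (j != i && design[i, j] > 0)
          z <- z + design[i, j] * drop(crossprod(Xd[[i]], tScores[[j]]))
        ui <- unitNorm(softKeep(z, keepX[[i]][h]))
        delta <- max(delta, max(abs(ui - u[[i]])))
        u[[i]] <- ui
        tScores[[i]] <- drop(Xd[[i]] %*% ui)
      }
      vNew <- unitNorm(Reduce(`+`, lapply(seq_len(K), function(i)
        cY[i] * drop(crossprod(Yd, tScores[[i]])))))
      delta <- max(delta, max(abs(vNew - v)))
      v <- vNew
      tY <- drop(Yd %*% v)
      obj <- c(obj, evalObj())
      if (delta < tol) break
      if (iter >= maxIter)
        stop(sprintf("component %d did not converge after %d iterations",
                     h, maxIter))
    }
    objective[[h]] <- obj
    for (i in seq_len(K)) {
      ti <- tScores[[i]]
      tss <- sum(ti^2)
      pl <- drop(crossprod(Xd[[i]], ti)) / tss
      Xd[[i]] <- Xd[[i]] - tcrossprod(ti, pl)
      fit[[i]]$U <- cbind(fit[[i]]$U, u[[i]])
      fit[[i]]$P <- cbind(fit[[i]]$P, pl)
      fit[[i]]$Tm <- cbind(fit[[i]]$Tm, ti)
    }
    tb <- Reduce(`+`, tScores) / K
    cl <- drop(crossprod(Yd, tb)) / sum(tb^2)
    Yd <- Yd - tcrossprod(tb, cl)
    V <- cbind(V, v)
    Cl <- cbind(Cl, cl)
    Tbar <- cbind(Tbar, tb)
  }
  list(fit = fit, V = V, C = Cl, Tbar = Tbar, objective = objective)
}

predMaps <- function(U, P) {
  if (ncol(U) == 0L)
    return(matrix(0, nrow(U), 0))
  U %*% solve(crossprod(P, U))
}

classCentroids <- function(Tm, y, classes) {
  out <- matrix(0, length(classes), ncol(Tm),
                dimnames = list(classes, colnames(Tm)))
  for (cl in classes)
    out[cl, ] <- colMeans(Tm[y == cl, , drop = FALSE])
  out
}

#' Fit a sparse PLS-DA model
#'
#' Encodes the class factor as a centered one-hot indicator and extracts
#' \code{ncomp} sparse latent components by alternating updates
#' \code{u = X'Yv} (soft-thresholded to exactly \code{keepX[h]} nonzeros,
#' survivors shrunk by the (keepX+1)-th largest magnitude, then
#' renormalized) and \code{v = Y'Xu}, iterated to loading convergence
#' (tolerance \code{tol}, at most \code{maxIter} iterations, error on
#' non-convergence). After each component, X and Y are deflated by
#' regression on the component score.
#'
#' @param X samples-by-features numeric matrix (column names = feature IDs).
#' @param y class labels (factor or coercible) with at least two classes
#'   present.
#' @param ncomp number of components; must satisfy
#'   \code{ncomp <= min(n - 1, p)}. \code{ncomp = 0} yields an empty model.
#' @param keepX per-component nonzero budget, recycled to \code{ncomp};
#'   values in [1, p]. Defaults to all features (dense PLS-DA).
#' @param scaleX also scale features to unit variance (default: center only).
#' @param tol,maxIter convergence control.
#' @return An \linkS4class{SplsModel}.
#' @examples
#' set.seed(1)
#' X <- cbind(sig = rep(0:1, each = 10) + rnorm(20, 0, .1),
#'            noise = rnorm(20))
#' fit <- splsdaFit(X, rep(c("control", "case"), each = 10),
#'                  ncomp = 1, keepX = 1)
#' which(loadings(fit)[, 1] != 0)
#' @export
splsdaFit <- function(X, y, ncomp, keepX = ncol(X), scaleX = FALSE,
                      tol = 1e-6, maxIter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("y must contain at least two classes")
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1L, p))
    stop("ncomp exceeds the rank bound min(n - 1, p)")
  keepX <- as.integer(rep_len(keepX, max(ncomp, 1L)))
  if (ncomp >= 1L && (any(keepX < 1L) || any(keepX > p)))
    stop("keepX values must lie in [1, ncol(X)]")
  cc <- centerColumns(X, scale = scaleX)
  Y <- oneHotIndicator(y)
  ymeans <- colMeans(Y)
  Yc <- sweep(Y, 2L, ymeans)
  classes <- colnames(Y)
  if (ncomp == 0L) {
    return(new("SplsModel", ncomp = 0L, keepX = integer(),
               loadings = matrix(0, p, 0, dimnames = list(colnames(X), NULL)),
               yloadings = matrix(0, length(classes), 0),
               scores = matrix(0, n, 0), xmeans = cc$mean, xscales = cc$scale,
               ymeans = ymeans, coef = matrix(0, p, length(classes),
                 dimnames = list(colnames(X), classes)),
               wstar = matrix(0, p, 0),
               centroids = matrix(0, length(classes), 0,
                 dimnames = list(classes, NULL)),
               classes = classes, features = colnames(X),
               objective = list()))
  }
  eng <- multiblockEngine(list(block = cc$X), Yc, ncomp,
                          list(block = keepX),
                          design = matrix(c(0, 1, 1, 0), 2L), tol = tol,
                          maxIter = as.integer(maxIter))
  b <- eng$fit[[1L]]
  cn <- sprintf("comp%d", seq_len(ncomp))
  dimnames(b$U) <- list(colnames(X), cn)
  dimnames(b$Tm) <- list(rownames(X), cn)
  wstar <- predMaps(b$U, b$P)
  coef <- wstar %*% t(eng$C)
  dimnames(coef) <- list(colnames(X), classes)
  new("SplsModel", ncomp = as.integer(ncomp), keepX = keepX,
      loadings = b$U,
      yloadings = matrix(eng$V, ncol = ncomp,
                         dimnames = list(classes, cn)),
      scores = b$Tm, xmeans = cc$mean, xscales = cc$scale, ymeans = ymeans,
      coef = coef, wstar = wstar,
      centroids = classCentroids(b$Tm, y, classes), classes = classes,
      features = colnames(X), objective = eng$objective)
}

predictScores <- function(Xc, coef, ymeans) {
  S <- sweep(Xc %*% coef, 2L, ymeans, "+")
  colnames(S) <- names(ymeans)
  S
}

pickClass <- function(S, classes) {
  # classes are sorted; ties.method "first" = lexicographically smaller
  factor(classes[max.col(S, ties.method = "first")], levels = classes)
}

#' Predict classes from a fitted sPLS-DA model
#'
#' Centers new samples with the training means, then either applies the
#' fitted indicator-regression map and takes the argmax over classes
#' (\code{max_dist}) or assigns the nearest training-class centroid in
#' component-score space (\code{centroid_dist}). Ties go to the
#' lexicographically smaller class label.
#'
#' @param model an \linkS4class{SplsModel}.
#' @param Xnew samples-by-features matrix with the training features.
#' @param distance \code{"max_dist"} (default) or \code{"centroid_dist"}.
#' @return List with \code{class} (factor) and \code{scores} (class score
#'   matrix: predicted indicators, or negated centroid distances).
#' @export
splsdaPredict <- function(model, Xnew,
                          distance = c("max_dist", "centroid_dist")) {
  distance <- match.arg(distance)
  Xnew <- as.matrix(Xnew)
  if (!is.null(colnames(Xnew))) {
    if (!all(model@features %in% colnames(Xnew)))
      stop("feature mismatch: new data lacks training features")
    Xnew <- Xnew[, model@features, drop = FALSE]
  } else if (ncol(Xnew) != length(model@features)) {
    stop("feature mismatch: wrong number of columns")
  }
  Xc <- sweep(sweep(Xnew, 2L, model@xmeans), 2L, model@xscales, "/")
  if (distance == "max_dist" || model@ncomp == 0L) {
    S <- predictScores(Xc, model@coef, model@ymeans)
  } else {
    Tn <- Xc %*% model@wstar
    D <- outer(rowSums(Tn^2), rowSums(model@centroids^2), "+") -
      2 * Tn %*% t(model@centroids)
    S <- -D
    colnames(S) <- model@classes
  }
  list(class = pickClass(S, model@classes), scores = S)
}

defaultDesign <- function(K, blockWeight = 0.1) {
  d <- matrix(blockWeight, K + 1L, K + 1L)
  d[, K + 1L] <- 1
  d[K + 1L, ] <- 1
  diag(d) <- 0
  d
}

#' Fit a multiblock (DIABLO-style) sparse PLS-DA model
#'
#' Extracts components jointly across omics blocks by block-coordinate
#' ascent on \code{sum_{i<j} c_ij cov(X_i u_i, X_j u_j)} with the class
#' indicator treated as an additional block (weight \code{c_iY = 1}). Each
#' block update is \code{u_i = sum_j c_ij X_i' t_j}, soft-thresholded to
#' exactly \code{keepX_i[h]} nonzeros and renormalized; sweeps repeat until
#' all loadings converge. Blocks are deflated on their own scores; the
#' indicator is deflated once per component on the mean block score (which
#' reduces exactly to the single-block sPLS-DA rule).
#'
#' @param blocks named list of samples-by-features matrices, sample-aligned.
#' @param y class labels, at least two classes.
#' @param ncomp shared component count.
#' @param keepX named list (per block) of per-component budgets, or a single
#'   vector recycled to every block. Defaults to all features per block.
#' @param design optional symmetric design matrix: either K x K (block-block
#'   weights; the outcome weights are set to 1) or (K+1) x (K+1) including
#'   the outcome block. Default block-block weight is 0.1.
#' @param scaleX,tol,maxIter as in \code{\link{splsdaFit}}.
#' @return A \linkS4class{DiabloModel}.
#' @export
diabloFit <- function(blocks, y, ncomp, keepX = NULL, design = NULL,
                      scaleX = FALSE, tol = 1e-6, maxIter = 100L) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  if (is.null(names(blocks)))
    names(blocks) <- sprintf("block%d", seq_along(blocks))
  blocks <- lapply(blocks, as.matrix)
  K <- length(blocks)
  n <- nrow(blocks[[1L]])
  for (bn in names(blocks)) {
    if (nrow(blocks[[bn]]) != n)
      stop("blocks are not sample-aligned (row counts differ)")
    if (!is.null(rownames(blocks[[bn]])) &&
        !identical(rownames(blocks[[bn]]), rownames(blocks[[1L]])))
      stop("blocks are not sample-aligned (row names differ)")
    if (is.null(colnames(blocks[[bn]])))
      colnames(blocks[[bn]]) <- sprintf("%s_V%d", bn,
                                        seq_len(ncol(blocks[[bn]])))
  }
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("y must contain at least two classes")
  if (is.null(design)) {
    design <- defaultDesign(K)
  } else {
    design <- as.matrix(design)
    if (nrow(design) == K) {
      d <- defaultDesign(K)
      d[seq_len(K), seq_len(K)] <- design
      design <- d
    }
    if (nrow(design) != K + 1L || ncol(design) != K + 1L)
      stop("design dimension must be K or K+1 (with the outcome block)")
    if (!isSymmetric(unname(design)))
      stop("design matrix must be symmetric")
    if (any(design < 0) || any(design > 1))
      stop("design entries must lie in [0, 1]")
    diag(design) <- 0
  }
  if (is.null(keepX)) keepX <- lapply(blocks, ncol)
  if (!is.list(keepX)) keepX <- setNames(rep(list(keepX), K), names(blocks))
  keepX <- lapply(names(blocks), function(bn) {
    k <- as.integer(rep_len(keepX[[bn]], ncomp))
    if (any(k < 1L) || any(k > ncol(blocks[[bn]])))
      stop(sprintf("keepX out of range for block '%s'", bn))
    k
  })
  names(keepX) <- names(blocks)
  if (ncomp > min(n - 1L, vapply(blocks, ncol, 1L)))
    stop("ncomp exceeds the rank bound")
  cc <- lapply(blocks, centerColumns, scale = scaleX)
  Y <- oneHotIndicator(y)
  ymeans <- colMeans(Y)
  Yc <- sweep(Y, 2L, ymeans)
  classes <- colnames(Y)
  eng <- multiblockEngine(lapply(cc, `[[`, "X"), Yc, ncomp, keepX,
                          design, tol = tol, maxIter = as.integer(maxIter))
  cn <- sprintf("comp%d", seq_len(ncomp))
  blockFits <- list()
  for (i in seq_len(K)) {
    bn <- names(blocks)[i]
    b <- eng$fit[[i]]
    dimnames(b$U) <- list(colnames(blocks[[bn]]), cn)
    dimnames(b$Tm) <- list(rownames(blocks[[bn]]), cn)
    wstar <- predMaps(b$U, b$P)
    coef <- wstar %*% t(eng$C)
    dimnames(coef) <- list(colnames(blocks[[bn]]), classes)
    blockFits[[bn]] <- list(
      loadings = b$U, scores = b$Tm, coef = coef, wstar = wstar,
      centroids = classCentroids(b$Tm, y, classes),
      xmeans = cc[[bn]]$mean, xscales = cc[[bn]]$scale,
      keepX = keepX[[bn]], features = colnames(blocks[[bn]]))
  }
  new("DiabloModel", ncomp = as.integer(ncomp), blocks = blockFits,
      design = design, classes = classes, ymeans = ymeans,
      objective = eng$objective)
}

#' Predict classes from a fitted multiblock model
#'
#' Computes per-block class scores exactly as \code{\link{splsdaPredict}}
#' does, then combines them: \code{average} takes the argmax of the mean
#' score matrix; \code{majority_vote} takes the plurality of per-block
#' argmax calls, falling back to the average rule on vote ties.
#'
#' @param model a \linkS4class{DiabloModel}.
#' @param blocksNew named list holding every training block.
#' @param scheme \code{"average"} (default) or \code{"majority_vote"}.
#' @param distance per-block distance, as in \code{\link{splsdaPredict}}.
#' @return List with \code{class}, \code{scores} (combined matrix) and
#'   \code{blockScores} (per-block matrices).
#' @export
diabloPredict <- function(model, blocksNew,
                          scheme = c("average", "majority_vote"),
                          distance = c("max_dist", "centroid_dist")) {
  scheme <- match.arg(scheme)
  distance <- match.arg(distance)
  miss <- setdiff(names(model@blocks), names(blocksNew))
  if (length(miss))
    stop("missing block(s): ", paste(miss, collapse = ", "))
  classes <- model@classes
  blockScores <- list()
  for (bn in names(model@blocks)) {
    b <- model@blocks[[bn]]
    sub <- new("SplsModel", ncomp = model@ncomp, keepX = b$keepX,
               loadings = b$loadings, yloadings = matrix(0, length(classes), model@ncomp),
               scores = b$scores, xmeans = b$xmeans, xscales = b$xscales,
               ymeans = model@ymeans, coef = b$coef, wstar = b$wstar,
               centroids = b$centroids, classes = classes,
               features = b$features, objective = list())
    blockScores[[bn]] <- splsdaPredict(sub, blocksNew[[bn]],
                                       distance = distance)$scores
  }
  avg <- Reduce(`+`, blockScores) / length(blockScores)
  if (scheme == "average") {
    cls <- pickClass(avg, classes)
  } else {
    votes <- vapply(blockScores, function(S)
      as.character(pickClass(S, classes)), character(nrow(avg)))
    votes <- matrix(votes, nrow = nrow(avg))
    picked <- vapply(seq_len(nrow(avg)), function(i) {
      tab <- table(votes[i, ])
      win <- names(tab)[tab == max(tab)]
      if (length(win) == 1L) win
      else classes[which.max(avg[i, ])]   # average fallback on vote ties
    }, character(1))
    cls <- factor(picked, levels = classes)
  }
  list(class = cls, scores = avg, blockScores = blockScores)
}

#' Extract the selected feature signature
#'
#' Per block, the union over components of features with a nonzero loading,
#' deduplicated in a stable order (first selecting component, then input
#' order), with each feature's maximum absolute loading.
#'
#' @param model an \linkS4class{SplsModel} or \linkS4class{DiabloModel}.
#' @return A \code{FeatureSignature}: list with \code{features} (named list
#'   of character vectors per block) and \code{table} (data.frame with
#'   block, feature, maxAbsLoading, firstComp).
#' @export
selectFeatures <- function(model) {
  blockLoadings <- if (is(model, "DiabloModel"))
    lapply(model@blocks, `[[`, "loadings")
  else list(block = model@loadings)
  tabs <- list()
  feats <- list()
  for (bn in names(blockLoadings)) {
    U <- blockLoadings[[bn]]
    if (ncol(U) == 0L || !nrow(U)) {
      feats[[bn]] <- character()
      next
    }
    nz <- U != 0
    sel <- which(rowSums(nz) > 0L)
    if (!length(sel)) {
      feats[[bn]] <- character()
      next
    }
    firstComp <- apply(nz[sel, , drop = FALSE], 1L, function(r) which(r)[1L])
    ord <- order(firstComp, sel)
    sel <- sel[ord]
    tabs[[bn]] <- data.frame(
      block = bn, feature = rownames(U)[sel],
      maxAbsLoading = apply(abs(U[sel, , drop = FALSE]), 1L, max),
      firstComp = firstComp[ord], row.names = NULL)
    feats[[bn]] <- rownames(U)[sel]
  }
  structure(list(features = feats,
                 table = if (length(tabs)) do.call(rbind, tabs)
                         else data.frame(block = character(),
                                         feature = character(),
                                         maxAbsLoading = numeric(),
                                         firstComp = integer())),
            class = "FeatureSignature")
}

#' @export
print.FeatureSignature <- function(x, ...) {
  cat("FeatureSignature:",
      paste(sprintf("%s=%d", names(x$features), lengths(x$features)),
            collapse = ", "),
      sprintf("(union %d)\n", sum(lengths(x$features))))
  invisible(x)
}

sparseTriplets <- function(U, block) {
  idx <- which(U != 0, arr.ind = TRUE)
  data.frame(block = block, feature = rownames(U)[idx[, 1L]],
             component = idx[, 2L], value = U[idx], row.names = NULL)
}

#' Serialize a fitted model to a JSON bundle
#'
#' Writes loadings as sparse (block, feature, component, value) triplets
#' plus the dense prediction maps needed to restore scoring exactly.
#'
#' @param model an \linkS4class{SplsModel} or \linkS4class{DiabloModel}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readModelJSON}}
#' @export
writeModelJSON <- function(model, path) {
  packBlock <- function(b) list(
    loadings = sparseTriplets(b$loadings, "x"),
    coef = b$coef, wstar = b$wstar, centroids = b$centroids,
    xmeans = b$xmeans, xscales = b$xscales, keepX = b$keepX,
    features = b$features)
  if (is(model, "DiabloModel")) {
    payload <- list(type = "diablo", ncomp = model@ncomp,
                    classes = model@classes, ymeans = model@ymeans,
                    design = model@design,
                    blocks = lapply(model@blocks, packBlock))
  } else {
    payload <- list(type = "splsda", ncomp = model@ncomp,
                    classes = model@classes, ymeans = model@ymeans,
                    block = packBlock(list(
                      loadings = model@loadings, coef = model@coef,
                      wstar = model@wstar, centroids = model@centroids,
                      xmeans = model@xmeans, xscales = model@xscales,
                      keepX = model@keepX, features = model@features)))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a model serialized with writeModelJSON
#'
#' @param path JSON file written by \code{\link{writeModelJSON}}.
#' @return The restored model object.
#' @export
readModelJSON <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  ncomp <- as.integer(js$ncomp)
  classes <- js$classes
  unpackBlock <- function(b) {
    p <- length(b$features)
    U <- matrix(0, p, ncomp, dimnames = list(b$features,
                                             sprintf("comp%d", seq_len(ncomp))))
    tr <- b$loadings
    if (length(tr) && nrow(tr))
      U[cbind(match(tr$feature, b$features), tr$component)] <- tr$value
    asMat <- function(m, rn, cn) {
      m <- matrix(unlist(m), nrow = length(rn), byrow = FALSE,
                  dimnames = list(rn, cn))
      m
    }
    coef <- matrix(as.numeric(b$coef), p, length(classes),
                   dimnames = list(b$features, classes))
    wstar <- matrix(as.numeric(b$wstar), p, ncomp)
    centroids <- matrix(as.numeric(b$centroids), length(classes), ncomp,
                        dimnames = list(classes, NULL))
    list(loadings = U, coef = coef, wstar = wstar, centroids = centroids,
         xmeans = setNames(as.numeric(b$xmeans), b$features),
         xscales = as.numeric(b$xscales), keepX = as.integer(b$keepX),
         features = b$features)
  }
  ymeans <- setNames(as.numeric(js$ymeans), classes)
  if (js$type == "diablo") {
    blocks <- lapply(js$blocks, unpackBlock)
    blocks <- lapply(blocks, function(b) c(b, list(scores = matrix(0, 0, ncomp))))
    new("DiabloModel", ncomp = ncomp, blocks = blocks,
        design = matrix(as.numeric(unlist(js$design)),
                        length(blocks) + 1L, length(blocks) + 1L),
        classes = classes, ymeans = ymeans, objective = list())
  } else {
    b <- unpackBlock(js$block)
    new("SplsModel", ncomp = ncomp, keepX = b$keepX, loadings = b$loadings,
        yloadings = matrix(0, length(classes), ncomp),
        scores = matrix(0, 0, ncomp), xmeans = b$xmeans,
        xscales = b$xscales, ymeans = ymeans, coef = b$coef,
        wstar = b$wstar, centroids = b$centroids, classes = classes,
        features = b$features, objective = list())
  }
}
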