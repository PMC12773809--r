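# Block-specific normalization/filtering. Assay-level functions take
# features-in-rows matrices (the OmicsBlock convention); the z-score pair
# takes samples-in-rows model matrices (the classifier convention).

#' Convert methylation beta-values to M-values
#'
#' \code{M = log2(beta / (1 - beta))} after clipping beta to
#' \code{[eps, 1 - eps]} so boundary proportions stay finite.
#'
#' @param beta numeric matrix (or vector) with entries in [0, 1].
#' @param eps clipping constant, default \code{1e-6}.
#' @return Matrix of M-values, same shape and dimnames.
#' @examples
#' betaToMvalue(matrix(c(0.5, 0.8), 1))   # 0 and 2
#' @export
betaToMvalue <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta values must be finite and within [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  attributes(out) <- attributes(beta)
  out
}

#' Inverse of the M-value transform
#' @param m numeric matrix of M-values.
#' @return Matrix of beta-values in (0, 1).
#' @export
mvalueToBeta <- function(m) {
  out <- 2^m / (1 + 2^m)
  attributes(out) <- attributes(m)
  out
}

#' Remove features with low raw counts
#'
#' Drops features (rows) whose unnormalized median count across samples is
#' strictly below \code{minMedian}; survivor order is preserved.
#'
#' @param counts nonnegative integer matrix, features in rows.
#' @param minMedian threshold, default 1 (median < 1 removed).
#' @return List with \code{counts} (filtered matrix, sample columns intact)
#'   and \code{removed} (character IDs or row indices of dropped features).
#' @export
filterLowCounts <- function(counts, minMedian = 1) {
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be nonnegative and finite")
  med <- apply(counts, 1L, median)
  keep <- med >= minMedian
  ids <- rownames(counts)
  removed <- if (is.null(ids)) which(!keep) else ids[!keep]
  list(counts = counts[keep, , drop = FALSE], removed = removed)
}

#' Median-of-ratios library size normalization
#'
#' The reference profile is the per-feature geometric mean over samples,
#' computed on features with no zero count; each sample's size factor is
#' the median, over those reference features, of count / reference; the
#' normalized matrix divides each sample by its factor.
#'
#' @param counts nonnegative count matrix, features in rows.
#' @param reference optional fixed reference profile (named numeric vector
#'   of per-feature geometric means); when supplied, size factors are
#'   computed against it instead of re-deriving it, which makes the
#'   normalization exactly scale-equivariant per sample.
#' @return List with \code{normalized} matrix, \code{sizeFactors}
#'   (positive, named by sample) and \code{reference}.
#' @examples
#' m <- matrix(c(2, 4, 10, 4, 8, 20), 3,
#'   dimnames = list(paste0("g", 1:3), c("a", "b")))
#' medianRatioNormalize(m)$sizeFactors   # 1/sqrt(2), sqrt(2)
#' @export
medianRatioNormalize <- function(counts, reference = NULL) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  if (is.null(reference)) {
    zeroFree <- rowSums(counts == 0) == 0L
    if (!any(zeroFree))
      stop("median-of-ratios normalization requires at least one feature ",
           "with all-positive counts")
    reference <- exp(rowMeans(log(counts[zeroFree, , drop = FALSE])))
    names(reference) <- rownames(counts)[zeroFree]
  }
  if (is.null(names(reference)) ||
      !all(names(reference) %in% rownames(counts)))
    stop("reference must be named by features present in counts")
  ratios <- sweep(counts[names(reference), , drop = FALSE], 1L,
                  reference, "/")
  sf <- apply(ratios, 2L, median)
  names(sf) <- colnames(counts)
  list(normalized = sweep(counts, 2L, sf, "/"), sizeFactors = sf,
       reference = reference)
}

#' Keep the k most variable features
#'
#' Ranks features (rows) by sample variance and keeps the \code{k} largest;
#' ties are broken by input order, and \code{k >= nrow} returns the input
#' unchanged.
#'
#' @param x numeric matrix, features in rows.
#' @param k positive integer.
#' @return List with \code{x} (filtered matrix, original feature order
#'   preserved) and \code{kept} (character IDs or indices).
#' @export
varianceTopK <- function(x, k) {
  if (k < 1) stop("k must be >= 1")
  p <- nrow(x)
  if (k >= p) {
    kept <- if (is.null(rownames(x))) seq_len(p) else rownames(x)
    return(list(x = x, kept = kept))
  }
  v <- apply(x, 1L, var)
  ord <- order(-v)            # stable: ties keep input order
  sel <- sort(ord[seq_len(k)])
  kept <- if (is.null(rownames(x))) sel else rownames(x)[sel]
  list(x = x[sel, , drop = FALSE], kept = kept)
}

#' Log2 transform and per-sample median centering
#'
#' For positive intensity matrices: take log2, then subtract each sample's
#' (column's) median so every sample has median 0.
#'
#' @param intensities positive matrix, features in rows.
#' @return Centered log2 matrix.
#' @export
log2MedianCenter <- function(intensities) {
  if (any(intensities <= 0) || any(!is.finite(intensities)))
    stop("intensities must be positive and finite")
  lg <- log2(intensities)
  sweep(lg, 2L, apply(lg, 2L, median))
}

#' Median centering of an already-log matrix
#' @param x matrix on the log scale, features in rows.
#' @return Per-sample median-centered matrix.
#' @export
medianCenter <- function(x) sweep(x, 2L, apply(x, 2L, median))

#' Fit per-feature z-score scaling on training samples
#'
#' Learns each feature's mean and standard deviation on the training matrix
#' only; zero-variance features are flagged and later mapped to 0.
#'
#' @param train numeric matrix, samples in rows, features in columns.
#' @return A \code{ScalerState} list: \code{mean}, \code{sd} (as learned),
#'   \code{constant} logical flags, \code{features}.
#' @export
zscoreFit <- function(train) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  structure(list(mean = mu, sd = sdv, constant = sdv == 0 | !is.finite(sdv),
                 features = colnames(train)),
            class = "ScalerState")
}

#' Apply a fitted z-score scaler
#'
#' @param state a \code{ScalerState} from \code{\link{zscoreFit}}.
#' @param x samples-in-rows matrix with the training feature columns.
#' @return Scaled matrix; constant training features become all-zero.
#' @export
zscoreApply <- function(state, x) {
  stopifnot(inherits(state, "ScalerState"))
  if (!is.null(state$features)) {
    if (is.null(colnames(x)) || !all(state$features %in% colnames(x)))
      stop("feature mismatch between scaler state and input matrix")
    x <- x[, state$features, drop = FALSE]
  } else if (ncol(x) != length(state$mean)) {
    stop("feature mismatch between scaler state and input matrix")
  }
  s <- ifelse(state$constant, 1, state$sd)
  out <- sweep(sweep(x, 2L, state$mean), 2L, s, "/")
  out[, state$constant] <- 0
  out
}

#' @export
print.ScalerState <- function(x, ...) {
  cat(sprintf("ScalerState: %d features (%d constant)\n",
              length(x$mean), sum(x$constant)))
  invisible(x)
}
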