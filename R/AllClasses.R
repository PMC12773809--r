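#' @import methods
#' @importFrom stats var median sd rnorm rbinom rnbinom quantile phyper
#'   p.adjust setNames aggregate qnorm pnorm runif ks.test t.test
#' @importFrom utils head read.delim write.table
#' @useDynLib topomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' OmicsBlock: one omics assay
#'
#' A single samples-by-features assay stored features-in-rows (Bioconductor
#' convention), with a modality tag (\code{"methylation"}, \code{"expression"},
#' \code{"proteomics"}, or any user label) used by the pipeline to pick the
#' right preprocessing chain.
#'
#' @slot assay numeric matrix, features in rows, samples in columns; dimnames
#'   are required and must be unique.
#' @slot modality single character tag.
#' @export
setClass("OmicsBlock",
  representation(assay = "matrix", modality = "character"))

setValidity("OmicsBlock", function(object) {
  a <- object@assay
  msg <- character()
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "assay must have feature rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(a))) msg <- c(msg, "duplicated feature IDs")
    if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicated sample IDs")
  }
  if (length(object@modality) != 1L) msg <- c(msg, "modality must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsBlock
#'
#' @param assay numeric matrix with feature rownames and sample colnames
#'   (features in rows).
#' @param modality character tag for the block.
#' @return An \linkS4class{OmicsBlock}.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' OmicsBlock(m, "proteomics")
#' @export
OmicsBlock <- function(assay, modality = "assay") {
  new("OmicsBlock", assay = as.matrix(assay), modality = modality)
}

#' MultiOmicsDataset: aligned blocks, labels, optional ground truth
#'
#' Holds one or more \linkS4class{OmicsBlock}s sharing a sample index, a
#' two-level class factor per sample, and (for synthetic data) the planted
#' truth: per-block signature feature IDs and network regulator IDs.
#'
#' @slot blocks named list of OmicsBlock, identical sample order.
#' @slot labels factor of per-sample classes, names = sample IDs.
#' @slot truth list; optionally \code{signature} (named list of character
#'   vectors per block) and \code{regulators} (character).
#' @export
setClass("MultiOmicsDataset",
  representation(blocks = "list", labels = "factor", truth = "list"))

setValidity("MultiOmicsDataset", function(object) {
  msg <- character()
  if (!length(object@blocks)) msg <- c(msg, "at least one block required")
  if (!all(vapply(object@blocks, is, TRUE, "OmicsBlock")))
    msg <- c(msg, "all blocks must be OmicsBlock objects")
  if (is.null(names(object@blocks)) || anyDuplicated(names(object@blocks)))
    msg <- c(msg, "blocks must be uniquely named")
  if (!length(msg)) {
    ref <- colnames(object@blocks[[1]]@assay)
    for (b in object@blocks)
      if (!identical(colnames(b@assay), ref)) {
        msg <- c(msg, "all blocks must share one sample order")
        break
      }
    if (length(object@labels) != length(ref))
      msg <- c(msg, "labels length must equal sample count")
    sig <- object@truth$signature
    if (!is.null(sig)) {
      for (bn in names(sig)) {
        if (!bn %in% names(object@blocks))
          msg <- c(msg, sprintf("truth block '%s' not a block", bn))
        else if (!all(sig[[bn]] %in% rownames(object@blocks[[bn]]@assay)))
          msg <- c(msg, sprintf("truth features missing from block '%s'", bn))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MultiOmicsDataset
#'
#' @param blocks named list of \linkS4class{OmicsBlock}s with identical
#'   sample columns.
#' @param labels factor (or coercible) of per-sample classes.
#' @param truth optional list with elements \code{signature} and
#'   \code{regulators} recording planted ground truth.
#' @return A \linkS4class{MultiOmicsDataset}.
#' @export
MultiOmicsDataset <- function(blocks, labels, truth = list()) {
  labels <- as.factor(labels)
  if (is.null(names(labels)) && length(blocks))
    names(labels) <- colnames(blocks[[1]]@assay)
  new("MultiOmicsDataset", blocks = blocks, labels = labels, truth = truth)
}

#' InteractionNetwork: weighted undirected interaction graph
#'
#' Wraps an \pkg{igraph} graph (simple, undirected, positive edge weights)
#' together with optional regulator flags (planted in synthetic networks or
#' derived from topology scoring).
#'
#' @slot graph an igraph object.
#' @slot regulators character vector of regulator node IDs (possibly empty).
#' @export
setClass("InteractionNetwork",
  representation(graph = "ANY", regulators = "character"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "parallel edges not allowed")
  if (is.null(igraph::V(g)$name)) msg <- c(msg, "nodes must be named")
  w <- igraph::E(g)$weight
  if (!is.null(w) && any(!is.finite(w) | w <= 0))
    msg <- c(msg, "edge weights must be positive and finite")
  if (!all(object@regulators %in% igraph::V(g)$name))
    msg <- c(msg, "regulators must be network nodes")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param edges either an igraph object or a data.frame whose first two
#'   columns are node IDs and whose optional third column is a positive
#'   weight.
#' @param regulators character vector of regulator node IDs.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
interactionNetwork <- function(edges, regulators = character()) {
  if (igraph::is_igraph(edges)) {
    g <- edges
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L) stop("edge table needs at least two columns")
    df <- data.frame(from = as.character(edges[[1]]),
                     to = as.character(edges[[2]]))
    if (ncol(edges) >= 3L) df$weight <- as.numeric(edges[[3]])
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
  }
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max", "ignore"))
  new("InteractionNetwork", graph = g, regulators = unique(regulators))
}

#' SimConfig: synthetic multi-omics generator settings
#'
#' Parameters of the two-class latent-component generator. Blocks share
#' \code{nLatent} standard-normal latent components; the first
#' \code{nDiscLatent} of them are shifted by \code{effectSize} in cases.
#' Signature features load on the latent components; everything else is
#' noise. See \code{\link{genMultiOmics}}.
#'
#' @slot nSamples positive integer.
#' @slot classProportions numeric pair (case, control) summing to 1.
#' @slot nLatent integer >= 1, shared latent components.
#' @slot nDiscLatent integer <= nLatent, class-linked components.
#' @slot effectSize nonnegative class shift on discriminative latent scores.
#' @slot blocks named list of per-block settings, each a list with
#'   \code{nFeatures}, \code{nSignature}, \code{noiseSd} and, for the counts
#'   block, \code{nbDispersion} and \code{libsizeSd}.
#' @slot interBlockCor correlation knob in [0, 1]: fraction of each signature
#'   feature's latent loading shared across blocks (1 = identical latent
#'   structure, the default; lower values add block-private latent noise).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(nSamples = "integer", classProportions = "numeric",
                 nLatent = "integer", nDiscLatent = "integer",
                 effectSize = "numeric", blocks = "list",
                 interBlockCor = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  cp <- object@classProportions
  if (length(cp) != 2L || any(cp <= 0) || any(cp >= 1) ||
      abs(sum(cp) - 1) > 1e-12)
    msg <- c(msg, "classProportions must be two fractions in (0,1) summing to 1")
  if (object@nLatent < 1L) msg <- c(msg, "nLatent must be >= 1")
  if (object@nDiscLatent > object@nLatent || object@nDiscLatent < 0L)
    msg <- c(msg, "nDiscLatent must be in [0, nLatent]")
  if (!is.finite(object@effectSize) || object@effectSize < 0)
    msg <- c(msg, "effectSize must be a nonnegative finite real")
  if (object@interBlockCor < 0 || object@interBlockCor > 1)
    msg <- c(msg, "interBlockCor must be in [0, 1]")
  for (bn in names(object@blocks)) {
    b <- object@blocks[[bn]]
    if (b$nSignature > b$nFeatures)
      msg <- c(msg, sprintf("block '%s': nSignature > nFeatures", bn))
    if (!is.finite(b$noiseSd) || b$noiseSd <= 0)
      msg <- c(msg, sprintf("block '%s': noiseSd must be positive", bn))
    if (!is.null(b$nbDispersion) && (!is.finite(b$nbDispersion) || b$nbDispersion <= 0))
      msg <- c(msg, sprintf("block '%s': nbDispersion must be positive", bn))
    if (!is.null(b$libsizeSd) && (!is.finite(b$libsizeSd) || b$libsizeSd < 0))
      msg <- c(msg, sprintf("block '%s': libsizeSd must be nonnegative", bn))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' Defaults mirror a down-scaled two-class multi-omics cohort: 305 samples at
#' roughly 70/30 class balance, two class-linked latent components with a
#' 1.5-SD case shift, three blocks (Gaussian M-values, negative-binomial
#' counts with log-normal library factors, Gaussian log2 intensities) each
#' carrying 20 signature features.
#'
#' @param nSamples,classProportions,nLatent,nDiscLatent,effectSize,seed see
#'   \linkS4class{SimConfig}.
#' @param blocks named list of per-block settings; see
#'   \linkS4class{SimConfig}. Defaults give methylation/expression/proteomics
#'   blocks of 500/500/200 features.
#' @param interBlockCor shared-loading fraction in [0,1]; see
#'   \linkS4class{SimConfig}.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nSamples = 60, seed = 1)
#' @export
simConfig <- function(nSamples = 305L,
                      classProportions = c(case = 0.7, control = 0.3),
                      nLatent = 2L, nDiscLatent = 2L, effectSize = 1.5,
                      blocks = list(
                        methylation = list(nFeatures = 500L, nSignature = 20L,
                                           noiseSd = 1),
                        expression = list(nFeatures = 500L, nSignature = 20L,
                                          noiseSd = 1, nbDispersion = 0.5,
                                          libsizeSd = 0.3),
                        proteomics = list(nFeatures = 200L, nSignature = 20L,
                                          noiseSd = 1)),
                      interBlockCor = 1, seed = 1L) {
  stopifnot(all(is.finite(classProportions)), is.finite(effectSize))
  new("SimConfig", nSamples = as.integer(nSamples),
      classProportions = classProportions, nLatent = as.integer(nLatent),
      nDiscLatent = as.integer(nDiscLatent), effectSize = effectSize,
      blocks = blocks, interBlockCor = interBlockCor, seed = as.integer(seed))
}

#' NetSimConfig: synthetic interaction-network generator settings
#'
#' Settings for the preferential-attachment network generator with planted
#' high-degree regulators biased toward signature nodes. See
#' \code{\link{genNetwork}}.
#'
#' @slot nNodes integer >= 3.
#' @slot attachment integer >= 1, edges added per arriving node.
#' @slot nRegulators integer < nNodes.
#' @slot regulatorSeedBias real >= 1, multiplier on the attachment weight of
#'   regulator--signature edges (1 = plain preferential attachment).
#' @slot seed integer RNG seed.
#' @export
setClass("NetSimConfig",
  representation(nNodes = "integer", attachment = "integer",
                 nRegulators = "integer", regulatorSeedBias = "numeric",
                 seed = "integer"))

setValidity("NetSimConfig", function(object) {
  msg <- character()
  if (object@nNodes < 3L) msg <- c(msg, "nNodes must be >= 3")
  if (object@attachment < 1L) msg <- c(msg, "attachment must be >= 1")
  if (object@nNodes <= object@attachment + 1L)
    msg <- c(msg, "nNodes too small for attachment parameter")
  if (object@nRegulators < 0L || object@nRegulators >= object@nNodes)
    msg <- c(msg, "nRegulators must be < nNodes")
  if (!is.finite(object@regulatorSeedBias) || object@regulatorSeedBias < 1)
    msg <- c(msg, "regulatorSeedBias must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a NetSimConfig
#'
#' @param nNodes,attachment,nRegulators,regulatorSeedBias,seed see
#'   \linkS4class{NetSimConfig}.
#' @return A validated \linkS4class{NetSimConfig}.
#' @examples
#' netSimConfig(nNodes = 100, seed = 3)
#' @export
netSimConfig <- function(nNodes = 500L, attachment = 3L, nRegulators = 20L,
                         regulatorSeedBias = 5, seed = 1L) {
  new("NetSimConfig", nNodes = as.integer(nNodes),
      attachment = as.integer(attachment),
      nRegulators = as.integer(nRegulators),
      regulatorSeedBias = regulatorSeedBias, seed = as.integer(seed))
}

#' SplsModel: fitted sparse PLS-DA model
#'
#' Per-component sparse feature loadings (exactly keepX nonzeros, unit L2
#' norm), outcome loadings, score vectors, and the regression map used for
#' prediction. Produced by \code{\link{splsdaFit}}.
#'
#' @slot ncomp integer number of components.
#' @slot keepX integer vector, per-component nonzero budget.
#' @slot loadings p x ncomp matrix of sparse feature loadings.
#' @slot yloadings class x ncomp matrix of outcome loadings.
#' @slot scores n x ncomp matrix of component scores.
#' @slot xmeans,xscales per-feature centering/scaling learned at fit.
#' @slot ymeans centered-indicator means.
#' @slot coef p x nclass regression map (max.dist prediction).
#' @slot wstar p x ncomp projection map to score space.
#' @slot centroids class x ncomp training-class centroids in score space.
#' @slot classes character class labels (sorted).
#' @slot features character feature IDs.
#' @slot objective list of per-component objective traces.
#' @export
setClass("SplsModel",
  representation(ncomp = "integer", keepX = "integer", loadings = "matrix",
                 yloadings = "matrix", scores = "matrix", xmeans = "numeric",
                 xscales = "numeric", ymeans = "numeric", coef = "matrix",
                 wstar = "matrix", centroids = "matrix", classes = "character",
                 features = "character", objective = "list"))

setValidity("SplsModel", function(object) {
  msg <- character()
  if (object@ncomp >= 1L) {
    nrm <- sqrt(colSums(object@loadings^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "feature loadings must have unit L2 norm")
    nz <- colSums(object@loadings != 0)
    if (any(nz > object@keepX))
      msg <- c(msg, "nonzero loading count exceeds keepX")
  }
  if (length(msg)) msg else TRUE
})

#' DiabloModel: fitted multiblock sparse PLS-DA model
#'
#' Per-block component stacks sharing \code{ncomp}, coupled through a
#' symmetric design matrix of block-to-block covariance weights (outcome
#' block weight fixed at 1). Produced by \code{\link{diabloFit}}.
#'
#' @slot ncomp shared component count.
#' @slot blocks named list of per-block fits (loadings, scores, coef, wstar,
#'   centroids, xmeans, xscales, keepX, features).
#' @slot design (K+1) x (K+1) design matrix including the outcome block.
#' @slot classes character class labels (sorted).
#' @slot ymeans centered-indicator means.
#' @slot objective numeric objective trace (one value per sweep across all
#'   components, non-decreasing within each component).
#' @export
setClass("DiabloModel",
  representation(ncomp = "integer", blocks = "list", design = "matrix",
                 classes = "character", ymeans = "numeric",
                 objective = "list"))

setValidity("DiabloModel", function(object) {
  msg <- character()
  for (bn in names(object@blocks)) {
    b <- object@blocks[[bn]]
    if (object@ncomp >= 1L) {
      nrm <- sqrt(colSums(b$loadings^2))
      if (any(abs(nrm - 1) > 1e-8))
        msg <- c(msg, sprintf("block '%s': loadings must be unit norm", bn))
      if (any(colSums(b$loadings != 0) > b$keepX))
        msg <- c(msg, sprintf("block '%s': nonzeros exceed keepX", bn))
    }
  }
  d <- object@design
  if (!isSymmetric(unname(d)) || any(d < 0) || any(d > 1) ||
      any(diag(d) != 0))
    msg <- c(msg, "design must be symmetric with zero diagonal and entries in [0,1]")
  if (length(msg)) msg else TRUE
})
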