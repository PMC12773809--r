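#' Accessors for topomics classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{assayMatrix} returns a block's features-by-samples matrix,
#' \code{modality} its tag, \code{sampleIDs}/\code{featureIDs} the dimnames,
#' \code{classLabels} the per-sample factor, \code{blockNames} the block
#' names, \code{truthSignature}/\code{truthRegulators} the planted ground
#' truth, \code{nComp}/\code{keepX}/\code{loadings}/\code{scores} the model
#' geometry, and \code{networkGraph}/\code{regulators} the graph and its
#' regulator flags.
#'
#' @param x a topomics object.
#' @param ... unused.
#' @return The requested component; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("assayMatrix", function(x, ...) standardGeneric("assayMatrix"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x, ...) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x, ...) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x, ...) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x, ...) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("blockNames", function(x, ...) standardGeneric("blockNames"))
#' @rdname accessors
#' @export
setGeneric("truthSignature", function(x, ...) standardGeneric("truthSignature"))
#' @rdname accessors
#' @export
setGeneric("truthRegulators", function(x, ...) standardGeneric("truthRegulators"))
#' @rdname accessors
#' @export
setGeneric("nComp", function(x, ...) standardGeneric("nComp"))
#' @rdname accessors
#' @export
setGeneric("keepX", function(x, ...) standardGeneric("keepX"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x, ...) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setGeneric("regulators", function(x, ...) standardGeneric("regulators"))

#' @rdname accessors
#' @export
setMethod("assayMatrix", "OmicsBlock", function(x, ...) x@assay)
#' @rdname accessors
#' @export
setMethod("modality", "OmicsBlock", function(x, ...) x@modality)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "OmicsBlock", function(x, ...) colnames(x@assay))
#' @rdname accessors
#' @export
setMethod("featureIDs", "OmicsBlock", function(x, ...) rownames(x@assay))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "MultiOmicsDataset",
          function(x, ...) colnames(x@blocks[[1]]@assay))
#' @rdname accessors
#' @export
setMethod("classLabels", "MultiOmicsDataset", function(x, ...) x@labels)
#' @rdname accessors
#' @export
setMethod("blockNames", "MultiOmicsDataset", function(x, ...) names(x@blocks))
#' @rdname accessors
#' @param name block name.
#' @export
setMethod("assayMatrix", "MultiOmicsDataset", function(x, name, ...) {
  x@blocks[[name]]@assay
})
#' @rdname accessors
#' @export
setMethod("truthSignature", "MultiOmicsDataset",
          function(x, ...) x@truth$signature)
#' @rdname accessors
#' @export
setMethod("truthRegulators", "MultiOmicsDataset",
          function(x, ...) x@truth$regulators)

#' Extract a block from a MultiOmicsDataset
#' @param x a MultiOmicsDataset.
#' @param i block name or index.
#' @return An \linkS4class{OmicsBlock}.
#' @export
setMethod("[[", "MultiOmicsDataset", function(x, i) x@blocks[[i]])

#' @rdname accessors
#' @export
setMethod("nComp", "SplsModel", function(x, ...) x@ncomp)
#' @rdname accessors
#' @export
setMethod("keepX", "SplsModel", function(x, ...) x@keepX)
#' @rdname accessors
#' @export
setMethod("loadings", "SplsModel", function(x, ...) x@loadings)
#' @rdname accessors
#' @export
setMethod("scores", "SplsModel", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("nComp", "DiabloModel", function(x, ...) x@ncomp)
#' @rdname accessors
#' @export
setMethod("blockNames", "DiabloModel", function(x, ...) names(x@blocks))
#' @rdname accessors
#' @export
setMethod("keepX", "DiabloModel",
          function(x, ...) lapply(x@blocks, `[[`, "keepX"))
#' @rdname accessors
#' @export
setMethod("loadings", "DiabloModel",
          function(x, ...) lapply(x@blocks, `[[`, "loadings"))
#' @rdname accessors
#' @export
setMethod("scores", "DiabloModel",
          function(x, ...) lapply(x@blocks, `[[`, "scores"))

#' @rdname accessors
#' @export
setMethod("networkGraph", "InteractionNetwork", function(x, ...) x@graph)
#' @rdname accessors
#' @export
setMethod("regulators", "InteractionNetwork", function(x, ...) x@regulators)
#' @rdname accessors
#' @export
setMethod("featureIDs", "InteractionNetwork",
          function(x, ...) igraph::V(x@graph)$name)

setMethod("show", "OmicsBlock", function(object) {
  cat(sprintf("OmicsBlock [%s]: %d features x %d samples\n",
              object@modality, nrow(object@assay), ncol(object@assay)))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  cat(sprintf("MultiOmicsDataset: %d samples, %d block(s)\n",
              length(object@labels), length(object@blocks)))
  for (bn in names(object@blocks))
    cat(sprintf("  %s [%s]: %d features\n", bn,
                object@blocks[[bn]]@modality,
                nrow(object@blocks[[bn]]@assay)))
  cat("  classes:",
      paste(sprintf("%s=%d", levels(object@labels), table(object@labels)),
            collapse = ", "), "\n")
  if (!is.null(object@truth$signature))
    cat("  planted signature:",
        sum(lengths(object@truth$signature)), "features\n")
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  cat(sprintf("InteractionNetwork: %d nodes, %d edges", igraph::vcount(g),
              igraph::ecount(g)))
  if (length(object@regulators))
    cat(sprintf(", %d regulator(s)", length(object@regulators)))
  cat("\n")
})

setMethod("show", "SplsModel", function(object) {
  cat(sprintf("SplsModel: %d component(s), %d features, classes %s\n",
              object@ncomp, length(object@features),
              paste(object@classes, collapse = "/")))
  cat("  keepX:", paste(object@keepX, collapse = ", "), "\n")
})

setMethod("show", "DiabloModel", function(object) {
  cat(sprintf("DiabloModel: %d component(s), %d block(s), classes %s\n",
              object@ncomp, length(object@blocks),
              paste(object@classes, collapse = "/")))
  for (bn in names(object@blocks))
    cat(sprintf("  %s: keepX %s\n", bn,
                paste(object@blocks[[bn]]$keepX, collapse = ", ")))
})
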