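# Synthetic two-class multi-omics cohorts and scale-free interaction
# networks with planted signatures/regulators, so the whole pipeline is
# exercisable offline.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

idPrefix <- function(blockName) {
  switch(blockName,
         methylation = "cg", expression = "gene", proteomics = "prot",
         gsub("[^a-zA-Z]", "", substr(blockName, 1, 4)))
}

#' Generate a synthetic two-class multi-omics dataset
#'
#' Samples share \code{nLatent} latent components drawn standard normal; the
#' first \code{nDiscLatent} components are shifted by \code{effectSize} in
#' case samples. In each block, the planted signature features are
#' \code{loading * latent + noise} (loadings uniform in +/-[0.5, 1.5],
#' assigned round-robin over components); all other features are pure noise.
#' The methylation block is emitted as Gaussian M-values, the expression
#' block as negative-binomial counts with mean
#' \code{exp(linear predictor) * library factor} (library factors log-normal
#' with sd \code{libsizeSd}), and the proteomics block as Gaussian log2
#' intensities. Identical configs (same seed) give bit-identical output.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{MultiOmicsDataset}; the truth slot carries the
#'   planted per-block signature feature IDs and the latent score matrix
#'   (for oracle checks).
#' @examples
#' d <- genMultiOmics(simConfig(nSamples = 40, seed = 7))
#' d
#' @export
genMultiOmics <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nSamples
    nCase <- round(n * config@classProportions[[1]])
    lab <- rep("control", n)
    lab[sample.int(n, nCase)] <- "case"
    labels <- factor(lab, levels = c("case", "control"))
    sampleIds <- sprintf("S%04d", seq_len(n))
    names(labels) <- sampleIds

    drawLatent <- function() {
      L <- matrix(rnorm(n * config@nLatent), n, config@nLatent)
      if (config@nDiscLatent >= 1L)
        L[labels == "case", seq_len(config@nDiscLatent)] <-
          L[labels == "case", seq_len(config@nDiscLatent), drop = FALSE] +
          config@effectSize
      L
    }
    L <- drawLatent()
    rho <- config@interBlockCor

    blocks <- list()
    truthSig <- list()
    for (bn in names(config@blocks)) {
      bc <- config@blocks[[bn]]
      p <- bc$nFeatures
      q <- bc$nSignature
      prefix <- idPrefix(bn)
      fids <- sprintf("%s%05d", prefix, seq_len(p))
      sigIdx <- sort(sample.int(p, q))
      # block-private latent share when interBlockCor < 1
      Lb <- if (rho >= 1) L else
        sqrt(rho) * L + sqrt(1 - rho) * drawLatent()
      comp <- if (q) rep_len(seq_len(config@nLatent), q) else integer()
      load <- runif(q, 0.5, 1.5) * sample(c(-1, 1), q, replace = TRUE)
      signal <- matrix(0, n, p)
      if (q) signal[, sigIdx] <- sweep(Lb[, comp, drop = FALSE], 2, load, "*")
      noise <- matrix(rnorm(n * p, 0, bc$noiseSd), n, p)
      if (!is.null(bc$nbDispersion)) {
        libsizeSd <- if (is.null(bc$libsizeSd)) 0 else bc$libsizeSd
        basal <- rnorm(p, 4, 1)
        eta <- sweep(signal + noise, 2, basal, "+")
        sf <- exp(rnorm(n, 0, libsizeSd))
        mu <- exp(eta) * sf
        X <- matrix(rnbinom(n * p, size = 1 / bc$nbDispersion, mu = mu), n, p)
      } else if (bn == "proteomics" || prefix == "prot") {
        basal <- rnorm(p, 10, 1)
        X <- sweep(signal + noise, 2, basal, "+")
      } else {
        basal <- rnorm(p, 0, 2)
        X <- sweep(signal + noise, 2, basal, "+")
      }
      dimnames(X) <- list(sampleIds, fids)
      blocks[[bn]] <- OmicsBlock(t(X), modality = bn)
      truthSig[[bn]] <- fids[sigIdx]
    }
    rownames(L) <- sampleIds
    MultiOmicsDataset(blocks, labels,
                      truth = list(signature = truthSig, latent = L))
  })
}

#' Generate a scale-free interaction network with planted regulators
#'
#' Builds an undirected preferential-attachment graph: after an initial
#' \code{attachment + 1} clique, each arriving node attaches to
#' \code{attachment} distinct existing nodes with probability proportional
#' to degree. The \code{nRegulators} regulator nodes occupy the earliest
#' arrival slots (so they become hubs), and the attachment weight of
#' regulator--signature node pairs is multiplied by
#' \code{regulatorSeedBias}; with bias 1 the process is plain preferential
#' attachment. Edge weights mimic interaction confidence scores (uniform in
#' [0.4, 0.99]). The graph is connected by construction; any residual
#' isolated component (possible only for degenerate inputs) is rewired to
#' the largest one.
#'
#' @param config a \code{\link{netSimConfig}}.
#' @param signatureNodes character IDs to embed as signature nodes; must fit
#'   in the non-regulator node space.
#' @param nodeNames optional character pool for the remaining node IDs
#'   (e.g. expression feature IDs so regulators resolve against that block);
#'   defaults to \code{node00001...}.
#' @return An \linkS4class{InteractionNetwork} with regulator flags set.
#' @examples
#' net <- genNetwork(netSimConfig(nNodes = 60, seed = 2),
#'                   signatureNodes = sprintf("gene%05d", 1:10))
#' net
#' @export
genNetwork <- function(config, signatureNodes = character(),
                       nodeNames = NULL) {
  stopifnot(is(config, "NetSimConfig"))
  validObject(config)
  n <- config@nNodes
  m <- config@attachment
  nReg <- config@nRegulators
  signatureNodes <- unique(as.character(signatureNodes))
  if (length(signatureNodes) > n - nReg)
    stop("signatureNodes do not fit in the non-regulator node space")
  withSeed(config@seed, {
    nOther <- n - length(signatureNodes)
    others <- if (is.null(nodeNames)) character()
              else setdiff(unique(as.character(nodeNames)), signatureNodes)
    if (length(others) < nOther)    # pad the pool with generic node IDs
      others <- c(others, sprintf("node%05d",
                                  seq_len(nOther - length(others))))
    others <- others[seq_len(nOther)]

    isReg <- logical(n)
    isReg[seq_len(nReg)] <- TRUE        # earliest arrivals -> hubs
    sigSlots <- sample(which(!isReg), length(signatureNodes))
    isSig <- logical(n)
    isSig[sigSlots] <- TRUE
    name <- character(n)
    name[sigSlots] <- signatureNodes
    name[!isSig] <- others

    deg <- integer(n)
    init <- seq_len(m + 1L)
    pairs <- which(upper.tri(matrix(0, m + 1L, m + 1L)), arr.ind = TRUE)
    from <- pairs[, 1L]
    to <- pairs[, 2L]
    deg[init] <- m
    edgesFrom <- vector("list", n)
    edgesTo <- vector("list", n)
    edgesFrom[[1L]] <- from
    edgesTo[[1L]] <- to
    bias <- config@regulatorSeedBias
    for (t in seq.int(m + 2L, n)) {
      w <- as.numeric(deg[seq_len(t - 1L)])
      if (bias > 1) {
        if (isSig[t]) w[isReg[seq_len(t - 1L)]] <- w[isReg[seq_len(t - 1L)]] * bias
        if (isReg[t]) w[isSig[seq_len(t - 1L)]] <- w[isSig[seq_len(t - 1L)]] * bias
      }
      tgt <- sample.int(t - 1L, m, replace = FALSE, prob = w)
      edgesFrom[[t]] <- rep.int(t, m)
      edgesTo[[t]] <- tgt
      deg[tgt] <- deg[tgt] + 1L
      deg[t] <- m
    }
    from <- unlist(edgesFrom)
    to <- unlist(edgesTo)
    if (bias > 1 && nReg && length(sigSlots)) {
      # extra regulator--signature edges so each pair's connection
      # probability is ~bias times the preferential-attachment baseline
      # P(r ~ s) ~ (m/2) / sqrt(t_r t_s) for arrival times t_r, t_s
      for (r in which(isReg)) {
        pAdd <- pmin(1, (bias - 1) * (m / 2) /
                       sqrt(pmax(r, 1) * pmax(sigSlots, 1)))
        hit <- sigSlots[runif(length(sigSlots)) < pAdd]
        if (length(hit)) {
          from <- c(from, rep.int(r, length(hit)))
          to <- c(to, hit)
        }
      }
    }
    g <- igraph::graph_from_edgelist(cbind(name[from], name[to]),
                                     directed = FALSE)
    # bring in any isolated slot (cannot occur for valid configs) and attach
    # stray components to the largest one
    missing <- setdiff(name, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                   name = missing)
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      big <- which.max(comp$csize)
      anchor <- igraph::V(g)$name[comp$membership == big][1L]
      for (k in seq_len(comp$no)) {
        if (k == big) next
        v <- igraph::V(g)$name[comp$membership == k][1L]
        g <- igraph::add_edges(g, c(v, anchor))
      }
    }
    g <- igraph::simplify(g)
    igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.4, 0.99), 3)
    interactionNetwork(g, regulators = name[isReg])
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits one TSV per block (feature IDs in the first column, sample IDs as
#' header), a labels TSV (\code{sample_id}, \code{class}), an edge-list TSV
#' (\code{node1}, \code{node2}, \code{weight}) and a \code{truth.json} with
#' the planted signature and regulator IDs.
#'
#' @param dataset a \linkS4class{MultiOmicsDataset}.
#' @param network optional \linkS4class{InteractionNetwork}.
#' @param dir output directory (created if absent).
#' @param orientation \code{"features_in_rows"} (default) or
#'   \code{"samples_in_rows"}.
#' @return Invisibly, a named character vector of written file paths.
#' @export
writeFixtureBundle <- function(dataset, network = NULL, dir,
                               orientation = c("features_in_rows",
                                               "samples_in_rows")) {
  orientation <- match.arg(orientation)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (bn in blockNames(dataset)) {
    p <- file.path(dir, paste0(bn, ".tsv"))
    writeOmicsMatrix(dataset[[bn]], p, orientation = orientation)
    paths[bn] <- p
  }
  labPath <- file.path(dir, "labels.tsv")
  write.table(data.frame(sample_id = sampleIDs(dataset),
                         class = as.character(classLabels(dataset))),
              labPath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["labels"] <- labPath
  if (!is.null(network)) {
    ep <- file.path(dir, "edges.tsv")
    writeEdgeList(network, ep)
    paths["edges"] <- ep
  }
  truth <- list(signature = truthSignature(dataset))
  if (!is.null(network)) truth$regulators <- regulators(network)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = FALSE, pretty = TRUE)
  paths["truth"] <- tp
  invisible(paths)
}

#' Closed-form AUC of the Gaussian two-class latent oracle
#'
#' For one latent dimension with a case shift of \code{delta} and unit
#' variances in both classes, the ROC AUC of the true latent score is
#' \code{pnorm(delta / sqrt(2))}: the distribution of the difference between
#' a case score and a control score is Normal(delta, 2).
#'
#' @param delta class shift on the latent score.
#' @return AUC in [0.5, 1) for delta >= 0.
#' @examples
#' latentOracleAUC(1.5)
#' @export
latentOracleAUC <- function(delta) pnorm(delta / sqrt(2))
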