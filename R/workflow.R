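# Configuration, delimited-matrix I/O and end-to-end orchestration:
# split -> train-fitted preprocessing -> tuning -> multiblock fit ->
# signature -> network topology -> model inputs -> grid search ->
# held-out evaluation (-> optional external validation).

#' Read a delimited omics matrix
#'
#' First column = row IDs, header = column IDs. Duplicated IDs, missing
#' values and ragged rows are rejected (the pipeline analyzes complete
#' cases only).
#'
#' @param path TSV/CSV path (delimiter inferred from the extension; tab by
#'   default).
#' @param orientation \code{"features_in_rows"} (default) or
#'   \code{"samples_in_rows"}; the returned block always stores features in
#'   rows.
#' @param modality modality tag for the block.
#' @return An \linkS4class{OmicsBlock}.
#' @export
readOmicsMatrix <- function(path,
                            orientation = c("features_in_rows",
                                            "samples_in_rows"),
                            modality = "assay") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated row ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn))
    stop("duplicated column ID(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in matrix: ", path)
  if (anyNA(m)) stop("missing values in matrix (complete cases required): ",
                     path)
  dimnames(m) <- list(ids, cn)
  if (orientation == "samples_in_rows") m <- t(m)
  OmicsBlock(m, modality = modality)
}

#' Write an OmicsBlock as a delimited matrix
#' @param block an \linkS4class{OmicsBlock} (or plain matrix, features in
#'   rows).
#' @param path output path.
#' @param orientation layout on disk.
#' @return Invisibly, \code{path}.
#' @export
writeOmicsMatrix <- function(block, path,
                             orientation = c("features_in_rows",
                                             "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- if (is(block, "OmicsBlock")) block@assay else as.matrix(block)
  if (orientation == "samples_in_rows") m <- t(m)
  idCol <- if (orientation == "features_in_rows") "feature_id" else
    "sample_id"
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- idCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table
#' @param path TSV with columns \code{sample_id} and \code{class}.
#' @return Named factor of classes.
#' @export
readLabelsTSV <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicated sample IDs in labels")
  setNames(factor(df[[2L]]), as.character(df[[1L]]))
}

#' Restrict blocks and labels to complete-case samples
#'
#' Keeps only samples measured in every block (and labelled); dropped IDs
#' are reported so they can be logged.
#'
#' @param blocks named list of \linkS4class{OmicsBlock}s (possibly with
#'   differing sample sets).
#' @param labels named factor of classes.
#' @return List with \code{blocks} (aligned to the common sample order of
#'   the first block), \code{labels}, \code{dropped} (character IDs).
#' @export
completeCases <- function(blocks, labels) {
  sampleSets <- lapply(blocks, function(b) colnames(b@assay))
  common <- Reduce(intersect, c(sampleSets, list(names(labels))))
  allIds <- unique(c(unlist(sampleSets), names(labels)))
  dropped <- setdiff(allIds, common)
  common <- sampleSets[[1L]][sampleSets[[1L]] %in% common]
  blocks <- lapply(blocks, function(b)
    OmicsBlock(b@assay[, common, drop = FALSE], modality = b@modality))
  list(blocks = blocks, labels = droplevels(labels[common]),
       dropped = dropped)
}

#' Deterministic per-stage seed derivation
#'
#' Hashes the stage name into an offset (polynomial string hash mod 2^20)
#' added to the global seed, so stages draw from independent, individually
#' reproducible streams.
#'
#' @param globalSeed integer global seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
deriveSeed <- function(globalSeed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1048576L
  as.integer((as.numeric(globalSeed) + h) %% .Machine$integer.max)
}

#' Assemble and validate a pipeline configuration
#'
#' @param blocks named list; per block a list with \code{path},
#'   \code{modality} (methylation/expression/proteomics/raw), optional
#'   \code{orientation}, optional preprocessing switches
#'   (\code{betaInput}, \code{varianceTopK}, \code{log2Transform}).
#' @param labels path to the labels TSV.
#' @param edges path to the interaction edge-list TSV.
#' @param outputDir output directory for reports.
#' @param seed global seed; every stage derives its own stream from it.
#' @param testFrac held-out fraction (default 0.2).
#' @param ncomp fixed component count, or NULL to tune (1..maxComp).
#' @param maxComp tuning range upper bound (default 6).
#' @param keepxGrid candidate keepX values for the integrative tuning.
#' @param tuneRepeats repeated CV partitions during tuning.
#' @param cvFolds folds for every cross-validation (default 5).
#' @param designWeight block-block design weight (default 0.1).
#' @param hnAlpha hidden-nodes significance cutoff (default 0.05).
#' @param npRestart,npPerm,npTopFrac network-propagation controls.
#' @param robustnessReps robustness simulations per fraction.
#' @param gbtGrid gradient-boosting grid (default
#'   \code{\link{gbtDefaultGrid}}).
#' @param bootB bootstrap resamples for metric CIs.
#' @param external optional list(blocks = named list of paths, labels =
#'   path) for external validation.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(blocks, labels, edges, outputDir, seed = 1L,
                           testFrac = 0.2, ncomp = NULL, maxComp = 6L,
                           keepxGrid = topomics::keepxGrid("integrative"),
                           tuneRepeats = 10L, cvFolds = 5L,
                           designWeight = 0.1, hnAlpha = 0.05,
                           npRestart = 0.5, npPerm = 1000L,
                           npTopFrac = 0.01, robustnessReps = 20L,
                           gbtGrid = gbtDefaultGrid(), bootB = 2000L,
                           external = NULL) {
  cfg <- list(blocks = blocks, labels = labels, edges = edges,
              outputDir = outputDir, seed = as.integer(seed),
              testFrac = testFrac, ncomp = ncomp, maxComp = maxComp,
              keepxGrid = keepxGrid, tuneRepeats = tuneRepeats,
              cvFolds = cvFolds, designWeight = designWeight,
              hnAlpha = hnAlpha, npRestart = npRestart, npPerm = npPerm,
              npTopFrac = npTopFrac, robustnessReps = robustnessReps,
              gbtGrid = as.data.frame(gbtGrid), bootB = bootB,
              external = external)
  validatePipelineConfig(cfg)
  class(cfg) <- "PipelineConfig"
  cfg
}

validatePipelineConfig <- function(cfg, checkPaths = TRUE) {
  need <- c("blocks", "labels", "edges", "outputDir", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("pipeline config lacks field(s): ", paste(miss, collapse = ", "))
  if (!length(cfg$blocks) || is.null(names(cfg$blocks)))
    stop("config blocks must be a named list")
  if (checkPaths) {
    for (bn in names(cfg$blocks)) {
      b <- cfg$blocks[[bn]]
      if (is.null(b$path) || !file.exists(b$path))
        stop(sprintf("block '%s': path missing or not found (%s)", bn,
                     if (is.null(b$path)) "NULL" else b$path))
    }
    for (f in c("labels", "edges"))
      if (!file.exists(cfg[[f]]))
        stop(sprintf("%s path not found: %s", f, cfg[[f]]))
  }
  if (cfg$testFrac <= 0 || cfg$testFrac >= 1)
    stop("testFrac must lie in (0, 1)")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   \code{\link{pipelineConfig}}; relative paths are resolved against the
#'   YAML file's directory.
#' @return A validated \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (bn in names(raw$blocks))
    raw$blocks[[bn]]$path <- resolve(raw$blocks[[bn]]$path)
  raw$labels <- resolve(raw$labels)
  raw$edges <- resolve(raw$edges)
  if (!is.null(raw$external)) {
    for (bn in names(raw$external$blocks))
      raw$external$blocks[[bn]] <- resolve(raw$external$blocks[[bn]])
    raw$external$labels <- resolve(raw$external$labels)
  }
  if (is.null(raw$outputDir)) raw$outputDir <- file.path(base, "output")
  args <- raw[intersect(names(raw), names(formals(pipelineConfig)))]
  do.call(pipelineConfig, args)
}

preprocessBlock <- function(block, cfg, trainIdx) {
  m <- block@assay
  steps <- character()
  if (isTRUE(cfg$betaInput)) {
    m <- betaToMvalue(m)
    steps <- c(steps, "betaToMvalue")
  }
  if (identical(block@modality, "expression")) {
    fl <- filterLowCounts(m)
    m <- fl$counts
    nr <- medianRatioNormalize(m)
    m <- log2(nr$normalized + 1)
    steps <- c(steps, sprintf("filterLowCounts(-%d)", length(fl$removed)),
               "medianRatioNormalize", "log2(+1)")
  }
  if (identical(block@modality, "proteomics") && isTRUE(cfg$log2Transform)) {
    m <- log2MedianCenter(m)
    steps <- c(steps, "log2MedianCenter")
  }
  if (!is.null(cfg$varianceTopK) && cfg$varianceTopK < nrow(m)) {
    # variance ranking learned on training samples only, applied to all
    keep <- varianceTopK(m[, trainIdx, drop = FALSE], cfg$varianceTopK)$kept
    m <- m[keep, , drop = FALSE]
    steps <- c(steps, sprintf("varianceTopK(%d)", cfg$varianceTopK))
  }
  list(block = OmicsBlock(m, modality = block@modality), steps = steps)
}

stageManifest <- function(manifest, stage, params, outputs = character(),
                          seed = NA_integer_, t0) {
  manifest$stages[[stage]] <- list(
    params = params, outputs = outputs, seed = seed,
    hashes = if (length(outputs))
      setNames(as.character(tools::md5sum(outputs)), basename(outputs))
    else NULL,
    elapsed = round(as.numeric(Sys.time()) - t0, 3))
  manifest
}

#' Run the full integrative pipeline
#'
#' Stage order: complete-case enforcement, stratified split, train-fitted
#' block preprocessing, (optional) component/keepX tuning, multiblock
#' sparse PLS-DA fit, signature extraction, network topology (hidden
#' nodes, propagation, stability suite), MO/TR/MO-TR model assembly, grid
#' search, held-out evaluation, and optional external validation. Every
#' stage draws from a seed derived from the global one, all reports are
#' written under \code{outputDir}, and the returned manifest records
#' parameters, seeds, output hashes and wall-clock per stage. Any stage
#' error aborts with the stage name attached.
#'
#' @param config a \code{PipelineConfig} (see \code{\link{pipelineConfig}}
#'   / \code{\link{readPipelineConfig}}).
#' @return A \code{RunManifest} list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  # structural validation only: a path that disappears after config
  # creation surfaces as an actionable error at the stage that needs it
  validatePipelineConfig(config, checkPaths = FALSE)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outputDir, f)
  manifest <- list(seed = config$seed, stages = list())
  stage <- "init"
  res <- tryCatch({
    # --- load + complete cases ------------------------------------------
    stage <- "load"
    t0 <- as.numeric(Sys.time())
    blocks <- lapply(names(config$blocks), function(bn) {
      b <- config$blocks[[bn]]
      readOmicsMatrix(b$path,
                      orientation = if (is.null(b$orientation))
                        "features_in_rows" else b$orientation,
                      modality = if (is.null(b$modality)) bn else b$modality)
    })
    names(blocks) <- names(config$blocks)
    labels <- readLabelsTSV(config$labels)
    cc <- completeCases(blocks, labels)
    blocks <- cc$blocks
    labels <- cc$labels
    manifest <- stageManifest(manifest, "load",
                              list(nSamples = length(labels),
                                   dropped = cc$dropped), t0 = t0)

    # --- split -----------------------------------------------------------
    stage <- "split"
    t0 <- as.numeric(Sys.time())
    splitSeed <- deriveSeed(config$seed, "split")
    plan <- stratifiedSplit(labels, testFrac = config$testFrac,
                            seed = splitSeed)
    trainIdx <- plan$train
    testIdx <- plan$test
    manifest <- stageManifest(manifest, "split",
                              list(train = length(trainIdx),
                                   test = length(testIdx)),
                              seed = splitSeed, t0 = t0)

    # --- preprocess (train-fitted) --------------------------------------
    stage <- "preprocess"
    t0 <- as.numeric(Sys.time())
    prepSteps <- list()
    for (bn in names(blocks)) {
      pr <- preprocessBlock(blocks[[bn]], config$blocks[[bn]], trainIdx)
      blocks[[bn]] <- pr$block
      prepSteps[[bn]] <- pr$steps
    }
    # samples-in-rows model matrices from here on
    Xall <- lapply(blocks, function(b) t(b@assay))
    manifest <- stageManifest(manifest, "preprocess", prepSteps, t0 = t0)

    # --- tune ------------------------------------------------------------
    stage <- "tune"
    t0 <- as.numeric(Sys.time())
    tuneSeed <- deriveSeed(config$seed, "tune")
    Xtrain <- lapply(Xall, function(m) m[trainIdx, , drop = FALSE])
    design <- defaultDesign(length(Xtrain), config$designWeight)
    if (is.null(config$ncomp)) {
      tn <- tuneNcomp(Xtrain, labels[trainIdx], maxComp = config$maxComp,
                      k = config$cvFolds, repeats = config$tuneRepeats,
                      seed = tuneSeed, design = design)
      ncomp <- tn$ncomp
    } else ncomp <- as.integer(config$ncomp)
    tk <- tuneKeepx(Xtrain, labels[trainIdx], ncomp = ncomp,
                    grid = config$keepxGrid, k = config$cvFolds,
                    repeats = config$tuneRepeats, seed = tuneSeed,
                    design = design)
    writeReportTSV(tk$surface, out("tuning_surface.tsv"))
    manifest <- stageManifest(manifest, "tune",
                              list(ncomp = ncomp, keepX = tk$keepX),
                              out("tuning_surface.tsv"), tuneSeed, t0)

    # --- integrate + signature ------------------------------------------
    stage <- "integrate"
    t0 <- as.numeric(Sys.time())
    model <- diabloFit(Xtrain, labels[trainIdx], ncomp = ncomp,
                       keepX = tk$keepX, design = design)
    signature <- selectFeatures(model)
    writeModelJSON(model, out("diablo_model.json"))
    writeReportTSV(signature$table, out("signature.tsv"))
    manifest <- stageManifest(manifest, "integrate",
                              list(ncomp = ncomp,
                                   signatureSize = lengths(signature$features)),
                              c(out("diablo_model.json"),
                                out("signature.tsv")), t0 = t0)

    # --- network topology ------------------------------------------------
    stage <- "nettopo"
    t0 <- as.numeric(Sys.time())
    net <- readEdgeList(config$edges)
    seeds <- intersect(unlist(signature$features, use.names = FALSE),
                       featureIDs(net))
    if (!length(seeds))
      stop("no signature feature maps onto the interaction network")
    netSeed <- deriveSeed(config$seed, "nettopo")
    hn <- hiddenNodes(net, seeds, alpha = config$hnAlpha)
    np <- networkPropagation(net, seeds, restart = config$npRestart,
                             nPerm = config$npPerm,
                             topFrac = config$npTopFrac, seed = netSeed)
    regulatorsFound <- sort(union(hn$node[hn$retained],
                                  np$node[np$retained]))
    stab <- stabilityReport(net, regulators = regulatorsFound,
                            reps = config$robustnessReps, seed = netSeed)
    writeReportTSV(hn, out("hidden_nodes.tsv"))
    writeReportTSV(np, out("network_propagation.tsv"))
    writeStabilityJSON(stab, out("stability.json"))
    manifest <- stageManifest(manifest, "nettopo",
                              list(nSeeds = length(seeds),
                                   nRegulators = length(regulatorsFound)),
                              c(out("hidden_nodes.tsv"),
                                out("network_propagation.tsv"),
                                out("stability.json")), netSeed, t0)

    # --- model inputs + grid search + evaluation -------------------------
    stage <- "classify"
    t0 <- as.numeric(Sys.time())
    inputs <- buildModelInputs(signature, regulatorsFound, Xall)
    clsSeed <- deriveSeed(config$seed, "classify")
    reports <- list()
    bestParams <- list()
    for (mn in c("MO", "TR", "MOTR")) {
      Xm <- inputs[[mn]]
      scaler <- zscoreFit(Xm[trainIdx, , drop = FALSE])
      Xs <- zscoreApply(scaler, Xm)
      gs <- gridSearchGbt(Xs[trainIdx, , drop = FALSE], labels[trainIdx],
                          paramGrid = config$gbtGrid, k = config$cvFolds,
                          seed = clsSeed)
      bestParams[[mn]] <- gs$best
      reports[[mn]] <- fitEval(Xs[trainIdx, , drop = FALSE],
                               labels[trainIdx],
                               Xs[testIdx, , drop = FALSE],
                               labels[testIdx], gs$best,
                               bootB = config$bootB, seed = clsSeed)
    }
    tbl <- metricsTable(reports)
    writeReportTSV(tbl, out("test_metrics.tsv"))
    manifest <- stageManifest(manifest, "classify",
                              list(best = bestParams,
                                   features = lapply(inputs[c("MO", "TR",
                                                              "MOTR")],
                                                     ncol)),
                              out("test_metrics.tsv"), clsSeed, t0)

    # --- optional external validation ------------------------------------
    if (!is.null(config$external)) {
      stage <- "external"
      t0 <- as.numeric(Sys.time())
      extBlocks <- lapply(config$external$blocks, function(p)
        t(readOmicsMatrix(p)@assay))
      extX <- do.call(cbind, unname(extBlocks))
      extY <- readLabelsTSV(config$external$labels)
      extSeed <- deriveSeed(config$seed, "external")
      extReports <- list()
      for (mn in c("MO", "TR", "MOTR")) {
        ev <- externalValidate(colnames(inputs[[mn]]),
                               inputs[[mn]][trainIdx, , drop = FALSE],
                               labels[trainIdx], extX,
                               extY[rownames(extX)], bestParams[[mn]],
                               featureBlocks = inputs$featureBlocks,
                               bootB = config$bootB, seed = extSeed)
        extReports[[mn]] <- ev$report
      }
      writeReportTSV(metricsTable(extReports), out("external_metrics.tsv"))
      manifest <- stageManifest(manifest, "external", list(),
                                out("external_metrics.tsv"), extSeed, t0)
    }
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(res) <- "RunManifest"
  jsonlite::write_json(unclass(res), out("manifest.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  res
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest (seed", x$seed, ")\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %ss\n", s, x$stages[[s]]$elapsed))
  invisible(x)
}
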