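#' Run the full synthetic-data analysis pipeline
#'
#' Replays the complete workflow on generated data: count simulation, a
#' UMI-resolution branch (read records, well assignment, UMI error
#' correction and counting, compared against the known molecule matrix),
#' cell/gene QC, the four normalization configurations (chip1/chip2 times
#' size factors/RUV), seed-target screening with cross-configuration
#' consensus and seed-seed interaction inference, dox classification from
#' the transgene, the genome-wide Spearman network with centralities and
#' seed-gene enrichment, and recovery metrics against the planted truth.
#'
#' @param config a [simulationConfig()]; its `rngSeed` drives every stage.
#' @param nPerm permutations for the dcor screen (default 499).
#' @param alpha significance level for the dcor screen.
#' @param minGenesPerCell,minCellsPerGene QC thresholds, scaled to the
#'   simulated matrix (defaults 50 and 10; the deep-sequencing defaults of
#'   [qcFilter()] suit genome-wide matrices).
#' @param umiGenes number of genes expanded to read records in the UMI
#'   branch (kept small; record expansion is the costly step).
#' @param spearmanThreshold edge threshold of the global network.
#' @param outDir optional directory; when given, the count matrix, edge
#'   lists and a JSON report are written there.
#' @return List of class `ehtnetReport` with elements `qc`, `umi`,
#'   `normalization`, `seedNetwork` (a [SeedNetwork-class]), `recovery`,
#'   `dox`, `globalNetwork` (a [GlobalNetwork-class]) and `enrichment`.
#' @export
runPipeline <- function(config = simulationConfig(),
                        nPerm = 499L, alpha = 0.05,
                        minGenesPerCell = 50L, minCellsPerGene = 10L,
                        umiGenes = 25L, spearmanThreshold = 0.25,
                        outDir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  sce <- simulateCounts(config)
  truth <- metadata(sce)$groundTruth
  counts <- assay(sce, "counts")
  roles <- rowData(sce)$role

  # --- UMI branch on a gene subset -----------------------------------------
  endo <- rownames(sce)[roles == "endogenous"]
  umiGeneSet <- head(endo, umiGenes)
  rr <- simulateReadRecords(sce, config, genes = umiGeneSet)
  aw <- assignWells(rr$records, unname(rr$whitelist))
  umiMat <- umiCountMatrix(aw$records)
  truthSub <- rr$truth[rownames(umiMat), , drop = FALSE]
  colnames(truthSub) <- unname(rr$whitelist[colnames(truthSub)])
  common <- intersect(colnames(umiMat), colnames(truthSub))
  umiErr <- sum(abs(umiMat[, common] - truthSub[, common])) /
    max(sum(truthSub[, common]), 1)
  umiReport <- list(nRecords = nrow(rr$records), discarded = aw$discarded,
                    genes = length(umiGeneSet),
                    relCountError = umiErr)

  # --- QC ------------------------------------------------------------------
  analysisGenes <- rownames(sce)[roles == "endogenous"]
  spikes <- rownames(sce)[roles == "spikein"]
  qcMat <- qcFilter(counts[analysisGenes, , drop = FALSE],
                    minGenesPerCell = minGenesPerCell,
                    minCellsPerGene = minCellsPerGene)
  keptCells <- colnames(qcMat)
  keptGenes <- rownames(qcMat)
  qcReport <- list(cellsKept = length(keptCells),
                   genesKept = length(keptGenes),
                   cellsRemoved = length(attr(qcMat, "removedCells")),
                   genesRemoved = length(attr(qcMat, "removedGenes")))

  # --- normalization: four configurations ----------------------------------
  batch <- colData(sce)[keptCells, "batch"]
  chips <- split(keptCells, batch)
  norm <- list()
  for (chip in names(chips)) {
    cells <- chips[[chip]]
    cnt <- counts[keptGenes, cells, drop = FALSE]
    norm[[paste0(chip, "-SF")]] <- sfNormalize(cnt)$normalized
    full <- counts[c(keptGenes, spikes), cells, drop = FALSE]
    norm[[paste0(chip, "-RUV")]] <-
      ruvNormalize(full, spikes, k = 1L)$adjusted[keptGenes, , drop = FALSE]
  }

  # --- seed network --------------------------------------------------------
  seeds <- intersect(config$seedGenes, keptGenes)
  results <- do.call(rbind, lapply(names(norm), function(cfg)
    findSeedTargets(norm[[cfg]], seeds, alpha = alpha, nPerm = nPerm,
                    rngSeed = config$rngSeed + match(cfg, names(norm)),
                    configId = cfg)))
  cons <- consensusEdges(results, minConfigs = 2L,
                         expectedConfigs = names(norm))
  inter <- inferSeedInteractions(norm, cons, seeds, minConfigs = 2L)
  net <- SeedNetwork(seeds, cons, inter)
  recovery <- recoveryMetrics(cons, truth$edges)

  # --- dox classification --------------------------------------------------
  doxCall <- classifyByTransgene(counts[, keptCells, drop = FALSE])
  doxTruth <- setNames(truth$dox, colnames(sce))[keptCells]
  doxAcc <- mean(doxCall == doxTruth)

  # --- global network (chips combined per normalization) -------------------
  mSF <- sfNormalize(counts[keptGenes, keptCells, drop = FALSE])$normalized
  mRUV <- ruvNormalize(counts[c(keptGenes, spikes), keptCells, drop = FALSE],
                       spikes, k = 1L)$adjusted[keptGenes, , drop = FALSE]
  gn <- buildSpearmanNetwork(mSF, mRUV, threshold = spearmanThreshold)
  enrichment <- NULL
  if (nrow(networkEdges(gn))) {
    gn <- networkCentralities(gn)
    ct <- centralityTable(gn)
    seedsInNet <- intersect(seeds, ct$gene)
    if (length(seedsInNet))
      enrichment <- lapply(c("degree", "betweenness", "eigen"),
                           function(ms) medianSplitBinomial(ct, seeds, ms))
  }

  report <- list(config = config, qc = qcReport, umi = umiReport,
                 normalization = names(norm), seedNetwork = net,
                 recovery = recovery,
                 dox = list(accuracy = doxAcc),
                 globalNetwork = gn, enrichment = enrichment)
  class(report) <- "ehtnetReport"

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCountMatrix(sce, file.path(outDir, "counts"))
    writeEdgeList(net, file.path(outDir, "seed_edges.tsv"))
    write.table(networkEdges(gn), file.path(outDir, "global_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    json <- list(
      qc = qcReport, umi = umiReport,
      seedEdges = nrow(seedEdges(net)),
      interactions = nrow(seedInteractions(net)),
      recovery = recovery[c("recall", "precision", "signAccuracy")],
      doxAccuracy = doxAcc,
      globalEdges = nrow(networkEdges(gn)),
      rngSeed = config$rngSeed)
    write_json(json, file.path(outDir, "report.json"), auto_unbox = TRUE,
               digits = NA)
  }
  report
}

#' @export
print.ehtnetReport <- function(x, ...) {
  cat("ehtnet pipeline report\n")
  cat("  QC: ", x$qc$cellsKept, " cells / ", x$qc$genesKept,
      " genes kept\n", sep = "")
  cat("  UMI branch: relative count error ",
      signif(x$umi$relCountError, 3), "\n", sep = "")
  cat("  Seed network: ", nrow(seedEdges(x$seedNetwork)), " edges, ",
      nrow(seedInteractions(x$seedNetwork)), " interactions\n", sep = "")
  cat("  Recovery: recall ", signif(x$recovery$recall, 3),
      ", precision ", signif(x$recovery$precision, 3),
      ", sign accuracy ", signif(x$recovery$signAccuracy, 3), "\n", sep = "")
  cat("  Dox classification accuracy: ", signif(x$dox$accuracy, 3), "\n",
      sep = "")
  cat("  Global network: ", nrow(networkEdges(x$globalNetwork)),
      " edges\n", sep = "")
  invisible(x)
}
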