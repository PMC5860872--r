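#' Default seed genes
#'
#' The 13 anchor transcription factors used for seed-based network inference:
#' the eight inducible TFs (heptad plus Cbfb) together with Gata1, Gfi1b,
#' Spi1, Ldb1 and Cbfa2t3.
#'
#' @export
defaultSeedGenes <- c("Runx1", "Gata2", "Tal1", "Fli1", "Lyl1", "Erg",
                      "Lmo2", "Cbfb", "Gata1", "Gfi1b", "Spi1", "Ldb1",
                      "Cbfa2t3")

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults define
#' the reference scenario used throughout the test suite: two chips
#' ("batches") of 150 cells, 13 seed genes, 50 planted signed targets of
#' which 10 load with opposite signs on Runx1 and Fli1 (the antagonistic
#' dual-sign motif), negative-binomial counts with shared dispersion,
#' log-normal library sizes, per-gene batch offsets, dropout, ERCC-like
#' spike-ins with cell-independent expected counts, and a dox-dependent
#' transgene.
#'
#' @param nCellsPerBatch cells per chip (two chips are generated).
#' @param nGenes total number of endogenous genes, including seeds, planted
#'   targets and the transgene.
#' @param nSpikeins number of spike-in control genes.
#' @param nRrna number of rRNA genes (used by the C1-style QC filter).
#' @param seedGenes character vector of seed gene names.
#' @param edgeTable `data.frame` with columns `seed`, `target`, `sign`
#'   (`"+"` or `"-"`) and `effect` (log-scale loading per unit of seed
#'   activity). When `NULL`, a default table with `nTargets` planted targets
#'   including `dualSignTargets` dual-sign (Runx1+/Fli1-) targets is built.
#' @param nTargets number of planted target genes for the default table.
#' @param dualSignTargets how many of the planted targets load positively on
#'   Runx1 and negatively on Fli1.
#' @param effectSize default |effect| for planted edges.
#' @param nbDispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); shared by all genes.
#' @param dropoutRate probability that an endogenous count is zeroed
#'   (independent per entry).
#' @param libsizeSigma sd of the log-normal cell library-size factor.
#' @param batchEffectSd sd of per-gene, per-batch log offsets.
#' @param stateEffectSd sd of per-gene state offsets for marker genes.
#' @param markerFraction fraction of background genes receiving state
#'   offsets (emulating lineage marker programs).
#' @param seedStateShift optional named list mapping seed gene to a numeric
#'   vector of per-state activity shifts; default none (seed activities are
#'   iid across seeds so that planted edges are the only seed-target
#'   dependencies).
#' @param baseMean median expected count of endogenous genes.
#' @param baseMeanSdLog sd of per-gene log base means.
#' @param spikeMean median expected spike-in count (cell-independent).
#' @param transgeneMean expected transgene count in dox-positive cells.
#' @param doxFraction fraction of dox-exposed cells.
#' @param umiLength UMI length in bases.
#' @param umiErrorRate per-base UMI substitution probability during read
#'   simulation.
#' @param barcodeLength well-barcode length in bases.
#' @param barcodeErrorRate fraction of read records whose well barcode is
#'   perturbed by 1-2 substitutions.
#' @param readSupportMean expected reads per molecule (truncated-at-1
#'   geometric amplification, shifted by `readSupportFloor - 1`).
#' @param readSupportFloor minimum read support per molecule; 1 reproduces
#'   the plain truncated geometric.
#' @param rngSeed integer seed making the whole generator deterministic.
#'
#' @return A list of class `SimulationConfig`.
#' @seealso [simulateCounts()], [simulateReadRecords()]
#' @export
simulationConfig <- function(nCellsPerBatch = 150L,
                             nGenes = 200L,
                             nSpikeins = 20L,
                             nRrna = 5L,
                             seedGenes = defaultSeedGenes,
                             edgeTable = NULL,
                             nTargets = 50L,
                             dualSignTargets = 10L,
                             effectSize = 1.0,
                             nbDispersion = 0.1,
                             dropoutRate = 0.1,
                             libsizeSigma = 0.2,
                             batchEffectSd = 0.1,
                             stateEffectSd = 0.5,
                             markerFraction = 0.1,
                             seedStateShift = NULL,
                             baseMean = 20,
                             baseMeanSdLog = 0.5,
                             spikeMean = 50,
                             transgeneMean = 50,
                             doxFraction = 0.5,
                             umiLength = 10L,
                             umiErrorRate = 0.005,
                             barcodeLength = 10L,
                             barcodeErrorRate = 0,
                             readSupportMean = 10,
                             readSupportFloor = 1L,
                             rngSeed = 1L) {
  stopifnot(nCellsPerBatch >= 1, nGenes >= 1, nSpikeins >= 1,
            umiLength >= 1, barcodeLength >= 1,
            nbDispersion > 0, libsizeSigma >= 0, batchEffectSd >= 0,
            readSupportMean >= readSupportFloor, readSupportFloor >= 1)
  if (dropoutRate < 0 || dropoutRate > 1)
    stop("dropoutRate must be in [0, 1]")
  if (umiErrorRate < 0 || umiErrorRate > 1)
    stop("umiErrorRate must be in [0, 1]")
  if (anyDuplicated(seedGenes))
    stop("seed gene names must be unique")

  if (is.null(edgeTable)) {
    edgeTable <- defaultEdgeTable(seedGenes, nTargets, dualSignTargets,
                                  effectSize)
  }
  edgeTable <- as.data.frame(edgeTable, stringsAsFactors = FALSE)
  stopifnot(all(c("seed", "target", "sign", "effect") %in% names(edgeTable)))
  if (!all(is.finite(edgeTable$effect)))
    stop("edge effect sizes must be finite")
  if (!all(edgeTable$sign %in% c("+", "-")))
    stop("edge signs must be '+' or '-'")
  if (!all(edgeTable$seed %in% seedGenes))
    stop("every edge seed must be a declared seed gene")
  if (anyDuplicated(edgeTable[, c("seed", "target")]))
    stop("duplicate (seed, target) edges")

  nNamed <- length(seedGenes) + length(unique(edgeTable$target)) + 1L
  if (nGenes < nNamed)
    stop("nGenes (", nGenes, ") is smaller than the number of named genes (",
         nNamed, ")")

  cfg <- list(nCellsPerBatch = as.integer(nCellsPerBatch),
              nGenes = as.integer(nGenes),
              nSpikeins = as.integer(nSpikeins), nRrna = as.integer(nRrna),
              seedGenes = seedGenes, edgeTable = edgeTable,
              nbDispersion = nbDispersion, dropoutRate = dropoutRate,
              libsizeSigma = libsizeSigma, batchEffectSd = batchEffectSd,
              stateEffectSd = stateEffectSd, markerFraction = markerFraction,
              seedStateShift = seedStateShift,
              baseMean = baseMean, baseMeanSdLog = baseMeanSdLog,
              spikeMean = spikeMean, transgeneMean = transgeneMean,
              doxFraction = doxFraction,
              umiLength = as.integer(umiLength),
              umiErrorRate = umiErrorRate,
              barcodeLength = as.integer(barcodeLength),
              barcodeErrorRate = barcodeErrorRate,
              readSupportMean = readSupportMean,
              readSupportFloor = as.integer(readSupportFloor),
              rngSeed = as.integer(rngSeed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# Round-robin single-sign targets across seeds, then dual-sign targets tied
# +effect to Runx1 and -effect to Fli1 (or the first two seeds).
defaultEdgeTable <- function(seedGenes, nTargets, dualSignTargets,
                             effectSize) {
  stopifnot(nTargets >= dualSignTargets, dualSignTargets >= 0)
  nSingle <- nTargets - dualSignTargets
  targets <- sprintf("Target%02d", seq_len(nTargets))
  rows <- list()
  if (nSingle > 0) {
    seedIdx <- rep_len(seq_along(seedGenes), nSingle)
    signs <- rep_len(c("+", "-"), nSingle)
    rows[[1]] <- data.frame(seed = seedGenes[seedIdx],
                            target = targets[seq_len(nSingle)],
                            sign = signs, effect = effectSize,
                            stringsAsFactors = FALSE)
  }
  if (dualSignTargets > 0) {
    sPos <- if ("Runx1" %in% seedGenes) "Runx1" else seedGenes[1]
    sNeg <- if ("Fli1" %in% seedGenes) "Fli1" else seedGenes[2]
    dual <- targets[nSingle + seq_len(dualSignTargets)]
    rows[[2]] <- data.frame(seed = rep(c(sPos, sNeg), each = dualSignTargets),
                            target = rep(dual, 2),
                            sign = rep(c("+", "-"), each = dualSignTargets),
                            effect = 0.8 * effectSize,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a gene-by-cell count matrix with planted network structure
#'
#' Generates negative-binomial UMI counts for two chips of cells. Each seed
#' gene follows a latent standard-normal activity (iid across seeds and
#' cells); planted targets load on the activities of their seeds in log-mean
#' space with the planted sign, so seed-target dependence is monotone and
#' detectable by rank and distance correlation. Library-size factors and
#' per-batch gene offsets act multiplicatively on endogenous genes; spike-in
#' controls have cell-independent expected counts; the transgene is expressed
#' only in dox-exposed cells; rRNA genes scale with library size.
#'
#' @param config a [simulationConfig()] object.
#' @return A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with assay `"counts"`, `rowData` columns `role`
#'   (`endogenous`/`spikein`/`transgene`/`rRNA`) and `baseMean`, `colData`
#'   columns `batch`, `state`, `dox`, `libsize`, and the ground truth in
#'   `metadata(.)$groundTruth` (`edges`, `activities`, `states`, `dox`,
#'   `config`).
#' @examples
#' sce <- simulateCounts(simulationConfig(nCellsPerBatch = 40, nGenes = 60,
#'                                        nTargets = 10, dualSignTargets = 2,
#'                                        rngSeed = 7))
#' table(SummarizedExperiment::rowData(sce)$role)
#' @export
simulateCounts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rngSeed)

  nCells <- 2L * config$nCellsPerBatch
  batch <- rep(c("chip1", "chip2"), each = config$nCellsPerBatch)
  cells <- sprintf("cell%03d", seq_len(nCells))

  states <- sample(c("Endo", "PreHSPC", "HSPC", "VSM"), nCells,
                   replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1))
  dox <- runif(nCells) < config$doxFraction

  seeds <- config$seedGenes
  targets <- unique(config$edgeTable$target)
  nBackground <- config$nGenes - length(seeds) - length(targets) - 1L
  background <- if (nBackground > 0)
    sprintf("Bg%03d", seq_len(nBackground)) else character(0)
  transgene <- "iTransgene"
  endoGenes <- c(seeds, targets, background, transgene)
  spikes <- sprintf("ERCC-%03d", seq_len(config$nSpikeins))
  rrna <- if (config$nRrna > 0) sprintf("Rrna%02d", seq_len(config$nRrna))
          else character(0)
  genes <- c(endoGenes, rrna, spikes)
  role <- c(rep("endogenous", length(endoGenes) - 1L), "transgene",
            rep("rRNA", length(rrna)), rep("spikein", length(spikes)))

  # latent seed activities, iid N(0,1) per (seed, cell); optional state shifts
  act <- matrix(rnorm(length(seeds) * nCells), length(seeds), nCells,
                dimnames = list(seeds, cells))
  if (!is.null(config$seedStateShift)) {
    stateLv <- c("Endo", "PreHSPC", "HSPC", "VSM")
    for (s in names(config$seedStateShift)) {
      sh <- config$seedStateShift[[s]]
      stopifnot(s %in% seeds, length(sh) == length(stateLv))
      act[s, ] <- act[s, ] + sh[match(states, stateLv)]
    }
  }

  libsize <- rlnorm(nCells, 0, config$libsizeSigma)
  baseMeans <- setNames(
    rlnorm(length(genes), log(config$baseMean), config$baseMeanSdLog), genes)
  baseMeans[spikes] <- rlnorm(length(spikes), log(config$spikeMean), 0.5)
  baseMeans[transgene] <- config$transgeneMean

  # log-scale mean matrix for endogenous genes
  logMu <- matrix(rep(log(baseMeans[endoGenes]), nCells),
                  length(endoGenes), nCells,
                  dimnames = list(endoGenes, cells))
  logMu[seeds, ] <- logMu[seeds, ] + act
  for (i in seq_len(nrow(config$edgeTable))) {
    e <- config$edgeTable[i, ]
    sgn <- if (e$sign == "+") 1 else -1
    logMu[e$target, ] <- logMu[e$target, ] + sgn * e$effect * act[e$seed, ]
  }
  # lineage marker programs on a fraction of background genes
  nMarker <- floor(length(background) * config$markerFraction)
  if (nMarker > 0 && config$stateEffectSd > 0) {
    markers <- background[seq_len(nMarker)]
    stateLv <- c("Endo", "PreHSPC", "HSPC", "VSM")
    shift <- matrix(rnorm(nMarker * 4, 0, config$stateEffectSd), nMarker, 4,
                    dimnames = list(markers, stateLv))
    logMu[markers, ] <- logMu[markers, ] + shift[, match(states, stateLv)]
  }
  # library size and batch offsets (endogenous only)
  logMu <- sweep(logMu, 2, log(libsize), "+")
  if (config$batchEffectSd > 0) {
    bOff <- matrix(rnorm(length(endoGenes) * 2, 0, config$batchEffectSd),
                   length(endoGenes), 2)
    logMu <- logMu + bOff[, match(batch, c("chip1", "chip2"))]
  }
  # transgene: only expressed under dox
  logMu[transgene, ] <- log(config$transgeneMean * libsize)
  mu <- exp(logMu)
  mu[transgene, !dox] <- 0

  size <- 1 / config$nbDispersion
  counts <- matrix(0L, length(genes), nCells, dimnames = list(genes, cells))
  counts[endoGenes, ] <- rnbinom(length(mu), mu = mu, size = size)
  if (length(rrna))
    counts[rrna, ] <- rnbinom(length(rrna) * nCells,
                              mu = outer(baseMeans[rrna], libsize),
                              size = size)
  counts[spikes, ] <- rnbinom(length(spikes) * nCells,
                              mu = rep(baseMeans[spikes], nCells),
                              size = size)
  if (config$dropoutRate > 0) {
    endoIdx <- which(genes %in% c(endoGenes, rrna))
    drop <- matrix(runif(length(endoIdx) * nCells) < config$dropoutRate,
                   length(endoIdx), nCells)
    counts[endoIdx, ][drop] <- 0L
  }
  storage.mode(counts) <- "integer"

  truth <- list(edges = config$edgeTable, activities = act, states = states,
                dox = dox, config = config)
  SingleCellExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(role = role, baseMean = unname(baseMeans[genes]),
                        row.names = genes),
    colData = DataFrame(batch = batch, state = states, dox = dox,
                        libsize = libsize, row.names = cells),
    metadata = list(groundTruth = truth))
}

randomDnaStrings <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  apply(m, 1, paste0, collapse = "")
}

#' Generate a well-barcode whitelist
#'
#' Greedy rejection sampling of DNA barcodes with pairwise Hamming distance
#' of at least `minDist`, so that the mismatch-tolerant well assignment is
#' well defined (as for designed plate barcode sets).
#'
#' @param n number of barcodes.
#' @param len barcode length.
#' @param minDist minimum pairwise Hamming distance.
#' @return Character vector of `n` distinct barcodes.
#' @export
makeWhitelist <- function(n, len = 10L, minDist = 5L) {
  out <- character(0)
  enc <- matrix(integer(0), len, 0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 2000L) stop("cannot build whitelist; relax minDist")
    batch <- unique(randomDnaStrings(max(64L, n), len))
    for (cand in batch) {
      ce <- utf8ToInt(cand)
      if (ncol(enc) == 0L || all(colSums(enc != ce) >= minDist)) {
        out <- c(out, cand)
        enc <- cbind(enc, ce)
        if (length(out) == n) break
      }
    }
  }
  out
}

#' Simulate gene-assigned read records with UMI and barcode errors
#'
#' Expands the true molecule counts of a simulation into per-read-group
#' records (well barcode, UMI, gene, read support). Every molecule receives
#' a random UMI and a read support drawn from a truncated-at-1 geometric
#' distribution (shifted by `readSupportFloor - 1`); per-base substitution
#' errors at `umiErrorRate` divert individual reads to satellite UMI records;
#' well barcodes are optionally perturbed.
#'
#' @param sce a [simulateCounts()] result (genes whose `rowData` role is
#'   `spikein` are excluded; molecules are the `counts` entries).
#' @param config the [simulationConfig()] used (for UMI/read parameters).
#' @param genes optional subset of genes to expand (keeps record sets small).
#' @return A list with `records` (a `data.table` with columns
#'   `well_barcode`, `umi`, `gene`, `reads`, plus `cell` for bookkeeping),
#'   `whitelist` (barcode per cell, named), and `truth` (the gene-by-cell
#'   molecule matrix that a perfect UMI counter would recover).
#' @export
simulateReadRecords <- function(sce, config, genes = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$rngSeed + 1L)
  counts <- assay(sce, "counts")
  keep <- rowData(sce)$role %in% c("endogenous", "transgene", "rRNA")
  counts <- counts[keep, , drop = FALSE]
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]

  nCells <- ncol(counts)
  whitelist <- setNames(makeWhitelist(nCells, config$barcodeLength),
                        colnames(counts))

  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(records = data.table(well_barcode = character(),
                                     umi = character(), gene = character(),
                                     reads = integer(), cell = character()),
                whitelist = whitelist, truth = counts))
  nMol <- counts[idx]
  molGene <- rep(rownames(counts)[idx[, 1]], nMol)
  molCell <- rep(colnames(counts)[idx[, 2]], nMol)
  M <- length(molGene)

  umis <- randomDnaStrings(M, config$umiLength)
  floorR <- config$readSupportFloor
  p <- 1 / (config$readSupportMean - floorR + 1)
  reads <- floorR + rgeom(M, p)

  L <- config$umiLength
  pErr <- 1 - (1 - config$umiErrorRate)^L
  nErr <- rbinom(M, reads, pErr)
  keepReads <- reads - nErr

  satGene <- rep(molGene, nErr)
  satCell <- rep(molCell, nErr)
  satParent <- rep(umis, nErr)
  nSat <- length(satParent)
  if (nSat > 0) {
    # number of substitutions per erroneous read: Binomial(L, e) truncated >=1
    pk <- dbinom(seq_len(L), L, config$umiErrorRate)
    k <- sample(seq_len(L), nSat, replace = TRUE, prob = pk)
    bases <- c("A", "C", "G", "T")
    alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars <- matrix(unlist(strsplit(satParent, "", fixed = TRUE), use.names = FALSE),
                    ncol = L, byrow = TRUE)
    one <- which(k == 1L)                    # fast path: single substitution
    if (length(one)) {
      pos <- sample.int(L, length(one), replace = TRUE)
      cur <- chars[cbind(one, pos)]
      chars[cbind(one, pos)] <-
        alt[cbind(match(cur, bases), sample.int(3L, length(one), TRUE))]
    }
    for (i in which(k > 1L)) {
      for (p2 in sample.int(L, k[i]))
        chars[i, p2] <- sample(setdiff(bases, chars[i, p2]), 1)
    }
    satUmi <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  } else satUmi <- character(0)

  dt <- rbind(
    data.table(cell = molCell, umi = umis, gene = molGene,
               reads = keepReads)[reads > 0],
    data.table(cell = satCell, umi = satUmi, gene = satGene, reads = 1L))
  dt <- dt[, .(reads = sum(reads)), by = .(cell, gene, umi)]
  dt[, well_barcode := whitelist[cell]]

  if (config$barcodeErrorRate > 0) {
    nPert <- rbinom(1, nrow(dt), config$barcodeErrorRate)
    if (nPert > 0) {
      rows <- sample.int(nrow(dt), nPert)
      bl <- config$barcodeLength
      pert <- vapply(dt$well_barcode[rows], function(b) {
        u <- strsplit(b, "")[[1]]
        for (p2 in sample.int(bl, sample(1:2, 1)))
          u[p2] <- sample(setdiff(c("A", "C", "G", "T"), u[p2]), 1)
        paste0(u, collapse = "")
      }, character(1), USE.NAMES = FALSE)
      dt[rows, well_barcode := pert]
    }
  }
  list(records = dt[, .(well_barcode, umi, gene, reads, cell)],
       whitelist = whitelist, truth = counts)
}

#' Simulate a plated cluster-composition count table
#'
#' Draws Poisson counts with mean `rate * plateTotal` for every
#' (line, dox, cluster) combination, emulating the plated single-cell
#' counting design behind the cluster-composition rate model: one plate per
#' line and dox condition, each cluster's count proportional to the plate
#' total.
#'
#' @param nLines number of cell lines (first line is named `"Empty"`).
#' @param nClusters number of cell clusters.
#' @param rateTable optional numeric matrix (`2 * nLines` rows ordered as all
#'   -dox lines then all +dox lines; `nClusters` columns) of per-cell rates;
#'   defaults to equal rates `1 / nClusters`.
#' @param plateTotals positive integer vector (recycled) of cells per plate.
#' @param rngSeed integer seed.
#' @return `data.frame` with columns `line`, `dox` (logical), `cluster`,
#'   `count`, `plateTotal`.
#' @export
simulateClusterCounts <- function(nLines = 10L, nClusters = 6L,
                                  rateTable = NULL, plateTotals = 100L,
                                  rngSeed = 1L) {
  stopifnot(nLines >= 1, nClusters >= 1)
  if (any(plateTotals <= 0)) stop("plate totals must be positive")
  lines <- c("Empty", sprintf("TF%d", seq_len(nLines - 1L)))
  clusters <- sprintf("C%d", seq_len(nClusters))
  if (is.null(rateTable))
    rateTable <- matrix(1 / nClusters, 2L * nLines, nClusters)
  rateTable <- as.matrix(rateTable)
  stopifnot(nrow(rateTable) == 2L * nLines, ncol(rateTable) == nClusters)
  if (any(rateTable < 0)) stop("rates must be non-negative")

  set.seed(rngSeed)
  dox <- rep(c(FALSE, TRUE), each = nLines)
  line <- rep(lines, 2L)
  totals <- rep_len(plateTotals, 2L * nLines)
  out <- do.call(rbind, lapply(seq_len(2L * nLines), function(i) {
    data.frame(line = line[i], dox = dox[i], cluster = clusters,
               count = rpois(nClusters, rateTable[i, ] * totals[i]),
               plateTotal = totals[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
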