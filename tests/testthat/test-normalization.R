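test_that("size factors implement median-of-ratios", {
  # 3x3 hand computation: geometric means per gene, per-cell median ratio
  m <- matrix(c(4, 8, 2,
                9, 3, 3,
                10, 5, 2), 3, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  byHand <- apply(m / geo, 2, median)
  expect_equal(unname(computeSizeFactors(m)), unname(byHand))

  # identical cells -> equal size factors; doubling a cell doubles its factor
  two <- cbind(a = c(5, 7, 9), b = c(5, 7, 9))
  rownames(two) <- paste0("g", 1:3)
  sf <- computeSizeFactors(two)
  expect_equal(sf[["a"]], sf[["b"]])
  tri <- cbind(two, c = 2 * two[, "a"])
  sf3 <- computeSizeFactors(tri)
  expect_equal(sf3[["c"]] / sf3[["a"]], 2)

  # per-cell scale equivariance (relative), whole-matrix scale invariance,
  # gene-permutation invariance
  set.seed(2)
  x <- matrix(rpois(60, 30) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  x5 <- x
  x5[, "c2"] <- x[, "c2"] * 5
  sf5 <- computeSizeFactors(x5)
  sf1 <- computeSizeFactors(x)
  expect_equal(unname((sf5["c2"] / sf5["c1"]) / (sf1["c2"] / sf1["c1"])), 5)
  expect_equal(computeSizeFactors(x * 5), computeSizeFactors(x))
  expect_equal(unname(computeSizeFactors(x[sample(10), ])),
               unname(computeSizeFactors(x)))
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  x <- matrix(rpois(300, 25) + 1, 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  expect_equal(unname(computeSizeFactors(x)),
               unname(DESeq2::estimateSizeFactorsForMatrix(x)),
               tolerance = 1e-10)
})

test_that("sparse matrices fall back to positive-count geometric means", {
  set.seed(3)
  x <- matrix(rpois(200, 5), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  x[cbind(1:20, rep(1:10, 2))] <- 0     # every gene has a zero somewhere
  expect_warning(sf <- computeSizeFactors(x), "positive-count")
  expect_true(all(sf > 0))
})

test_that("RUV removes a planted cell-wise nuisance factor", {
  set.seed(5)
  nGenes <- 60; nCells <- 80; nCtrl <- 12
  base <- matrix(rpois(nGenes * nCells, 50), nGenes, nCells,
                 dimnames = list(c(sprintf("ctrl%02d", 1:nCtrl),
                                   sprintf("g%02d", 1:(nGenes - nCtrl))),
                                 paste0("c", 1:nCells)))
  nuis <- exp(rnorm(nCells, 0, 0.6))
  counts <- round(sweep(base, 2, nuis, "*"))
  ctrl <- sprintf("ctrl%02d", 1:nCtrl)

  out <- ruvNormalize(counts, ctrl, k = 1)
  corAfter <- apply(out$adjusted, 1, function(r) cor(r, log(nuis)))
  corBefore <- apply(log(counts + 1), 1, function(r) cor(r, log(nuis)))
  expect_gt(mean(abs(corBefore)), 0.8)
  expect_lt(mean(abs(corAfter)), 0.2)

  # top singular value of the control submatrix strictly decreases
  svBefore <- svd(log(counts + 1)[ctrl, ] -
                  rowMeans(log(counts + 1)[ctrl, ]))$d
  adjC <- out$adjusted[ctrl, ] - rowMeans(out$adjusted[ctrl, ])
  svAfter <- svd(adjC)$d
  expect_lt(svAfter[1], svBefore[1])

  expect_error(ruvNormalize(counts, ctrl, k = 0), "at least 1")
  expect_error(ruvNormalize(counts, ctrl[1], k = 1), "control genes")
})

test_that("nuisance-free data keep their planted signal after RUV", {
  cfg <- simulationConfig(nCellsPerBatch = 100, nGenes = 40, nTargets = 6,
                          dualSignTargets = 0, libsizeSigma = 0,
                          batchEffectSd = 0, dropoutRate = 0, rngSeed = 13)
  sce <- simulateCounts(cfg)
  counts <- SummarizedExperiment::assay(sce, "counts")
  spikes <- rownames(sce)[SummarizedExperiment::rowData(sce)$role == "spikein"]
  adj <- ruvNormalize(counts, spikes, k = 1)$adjusted
  truth <- S4Vectors::metadata(sce)$groundTruth$edges
  for (i in seq_len(nrow(truth))) {
    rBefore <- cor(log(counts[truth$seed[i], ] + 1),
                   log(counts[truth$target[i], ] + 1), method = "spearman")
    rAfter <- cor(adj[truth$seed[i], ], adj[truth$target[i], ],
                  method = "spearman")
    expect_lt(abs(rAfter - rBefore), 0.15)
    expect_identical(sign(rAfter), sign(rBefore))
  }
})

test_that("HVG selection returns exactly nTop genes and finds planted variance", {
  set.seed(12)
  nGenes <- 100; nCells <- 60
  mu <- runif(nGenes, 2, 50)            # spread of gene means
  m <- matrix(rnorm(nGenes * nCells, rep(mu, nCells),
                    rep(sqrt(mu), nCells)), nGenes, nCells,
              dimnames = list(sprintf("g%03d", 1:nGenes), NULL))
  # plant 10 genes far above the trend, spread through the interior of the
  # mean range (local regression absorbs excess variance at the edges)
  hv <- names(sort(setNames(mu, rownames(m))))[seq(25, 70, 5)]
  muHv <- mu[match(hv, rownames(m))]
  m[hv, ] <- rnorm(10 * nCells, rep(muHv, nCells),
                   rep(sqrt(25 * muHv), nCells))
  out <- hvgPca(m, nTop = 20, nPc = 2)
  expect_identical(length(out$genes), 20L)
  expect_true(all(hv %in% out$genes))

  # nTop = gene count reduces to plain PCA on everything
  all <- hvgPca(m, nTop = nGenes, nPc = 2)
  expect_identical(length(all$genes), as.integer(nGenes))
  expect_equal(abs(all$scores[, 1]),
               abs(pcaScores(t(m), 2)$scores[, 1]))

  expect_error(hvgPca(m, nTop = nGenes + 1), "exceeds")
})
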