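# small helper: matrix with one strong planted seed->target edge
plantedMatrix <- function(n = 150, beta = 1, seedName = "S", rngSeed = 1) {
  set.seed(rngSeed)
  act <- rnorm(n)
  s <- rnbinom(n, mu = exp(3 + act), size = 10)
  tgt <- rnbinom(n, mu = exp(3 + beta * act), size = 10)
  null1 <- rnbinom(n, mu = 20, size = 10)
  null2 <- rnbinom(n, mu = 20, size = 10)
  m <- rbind(s, tgt, null1, null2)
  rownames(m) <- c(seedName, "T1", "N1", "N2")
  m
}

test_that("the dcor screen recovers a planted edge with its direction", {
  m <- plantedMatrix()
  res <- findSeedTargets(m, "S", nPerm = 199, rngSeed = 3, adjust = "none")
  hit <- res[res$target == "T1", ]
  expect_true(hit$significant)
  expect_identical(hit$direction, "positive")
  expect_gt(hit$dcor, 0.5)
  expect_false("S" %in% res$target)      # no self-pair

  neg <- plantedMatrix(beta = -1, rngSeed = 4)
  resN <- findSeedTargets(neg, "S", nPerm = 199, rngSeed = 3,
                          adjust = "none")
  expect_identical(resN[resN$target == "T1", "direction"], "negative")

  expect_error(findSeedTargets(m, "absent", nPerm = 9), "absent")
})

test_that("permutation p-values are calibrated for null genes", {
  set.seed(9)
  n <- 80
  m <- rbind(S = rnbinom(n, mu = 20, size = 10),
             matrix(rnbinom(40 * n, mu = 20, size = 10), 40, n,
                    dimnames = list(sprintf("N%02d", 1:40), NULL)))
  res <- findSeedTargets(m, "S", nPerm = 99, rngSeed = 5, adjust = "none")
  # raw p-values of independent genes are roughly uniform
  expect_gt(mean(res$pvalue > 0.5), 0.3)
  expect_lt(mean(res$pvalue < 0.05), 0.20)
  expect_identical(nrow(res), 40L)
})

test_that("direction falls back to 'other' for weak Pearson evidence", {
  set.seed(31)
  n <- 20
  repeat {   # draw a pair with |r| small enough that the t-test p > 0.05
    m <- rbind(S = rnorm(n), T1 = rnorm(n))
    r <- cor(m["S", ], m["T1", ])
    p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    if (p > 0.2) break
  }
  res <- findSeedTargets(m, "S", nPerm = 19, rngSeed = 1, adjust = "none")
  expect_identical(res$direction, "other")
})

test_that("consensus applies the 2-of-4 rule and direction conflicts", {
  row <- function(cfg, sig, dir, s = "S", t = "T1")
    data.frame(seed = s, target = t, dcor = 0.5, pvalue = 0.001,
               padj = 0.001, significant = sig, direction = dir,
               config = cfg, stringsAsFactors = FALSE)
  cfgs <- c("chip1-SF", "chip1-RUV", "chip2-SF", "chip2-RUV")

  one <- row(cfgs[1], TRUE, "positive")
  expect_identical(nrow(consensusEdges(one)), 0L)        # 1 of 4: dropped

  three <- rbind(row(cfgs[1], TRUE, "positive"),
                 row(cfgs[2], TRUE, "positive"),
                 row(cfgs[3], TRUE, "negative"))
  outc <- consensusEdges(three)
  expect_identical(outc$direction, "other")              # conflict
  expect_identical(outc$nConfigs, 3L)

  two <- rbind(row(cfgs[1], TRUE, "positive"),
               row(cfgs[4], TRUE, "positive"),
               row(cfgs[2], FALSE, "other"))
  out2 <- consensusEdges(two)
  expect_identical(out2$direction, "positive")
  expect_identical(out2$nConfigs, 2L)

  mixed <- rbind(row(cfgs[1], TRUE, "positive"),
                 row(cfgs[2], TRUE, "other"))
  expect_identical(consensusEdges(mixed)$direction, "other")

  expect_error(consensusEdges(one, expectedConfigs = cfgs[-1]), "unknown")
})

test_that("interaction inference detects planted suppression, not copies or noise", {
  makeConfigs <- function(build, nConfig = 4, n = 150) {
    out <- list()
    for (i in seq_len(nConfig)) out[[paste0("cfg", i)]] <- build(i, n)
    out
  }
  edges <- data.frame(seed = c("S1", "S2"), target = c("G1", "G1"),
                      direction = c("positive", "negative"),
                      nConfigs = 4L, meanDcor = 0.5)

  # antagonistic pair: G1 loads +1 on S1 and -1 on S2; conditioning on the
  # other seed removes masking noise, so both associations strengthen
  suppress <- makeConfigs(function(i, n) {
    set.seed(100 + i)
    a1 <- rnorm(n); a2 <- rnorm(n)
    rbind(S1 = rnbinom(n, mu = exp(3 + a1), size = 20),
          S2 = rnbinom(n, mu = exp(3 + a2), size = 20),
          G1 = rnbinom(n, mu = exp(3 + a1 - a2), size = 20))
  })
  it <- inferSeedInteractions(suppress, edges, c("S1", "S2"))
  expect_identical(nrow(it), 1L)
  expect_identical(it$targets, "G1")

  # mutually independent triple: false-call probability is bounded well
  # below the (near-certain) planted-suppression detection rate
  falseCalls <- vapply(1:12, function(rep) {
    indep <- makeConfigs(function(i, n) {
      set.seed(1000 * rep + i)
      rbind(S1 = rnbinom(n, mu = 20, size = 20),
            S2 = rnbinom(n, mu = 20, size = 20),
            G1 = rnbinom(n, mu = 20, size = 20))
    })
    nrow(inferSeedInteractions(indep, edges, c("S1", "S2"))) > 0
  }, logical(1))
  expect_lt(mean(falseCalls), 0.5)

  # s2 a pure copy of s1: conditioning annihilates, no increase
  copies <- makeConfigs(function(i, n) {
    set.seed(300 + i)
    a <- rnorm(n)
    s <- rnbinom(n, mu = exp(3 + a), size = 20)
    rbind(S1 = s, S2 = s, G1 = rnbinom(n, mu = exp(3 + a), size = 20))
  })
  expect_identical(nrow(inferSeedInteractions(copies, edges,
                                              c("S1", "S2"))), 0L)
})

test_that("display filter keeps interacting seeds and multi-seed targets", {
  edges <- data.frame(
    seed = c("S1", "S2", "S1", "S3"),
    target = c("G1", "G1", "G2", "G3"),
    direction = "positive", nConfigs = 2L, meanDcor = 0.4,
    stringsAsFactors = FALSE)
  inter <- data.frame(seed1 = "S1", seed2 = "S2", nConfigs = 2L,
                      targets = "G1", stringsAsFactors = FALSE)
  net <- SeedNetwork(c("S1", "S2", "S3"), edges, inter)
  filt <- displayFilter(net)
  expect_identical(sort(seedGenes(filt)), c("S1", "S2"))   # S3 isolated
  expect_identical(unique(seedEdges(filt)$target), "G1")   # G2, G3 dropped

  empty <- SeedNetwork(character(0),
                       edges[0, ], inter[0, ])
  expect_identical(nrow(seedEdges(displayFilter(empty))), 0L)
})

test_that("SeedNetwork validity catches malformed edges", {
  edges <- data.frame(seed = "X", target = "G", direction = "sideways",
                      nConfigs = 2L, meanDcor = 0.4)
  expect_error(SeedNetwork("S", edges), "positive/negative/other")
})

test_that("transgene classification matches planted dox status", {
  cfg <- simulationConfig(nCellsPerBatch = 80, nGenes = 40, nTargets = 5,
                          dualSignTargets = 0, dropoutRate = 0,
                          transgeneMean = 80, rngSeed = 17)
  sce <- simulateCounts(cfg)
  counts <- SummarizedExperiment::assay(sce, "counts")
  call <- classifyByTransgene(counts)
  truth <- S4Vectors::metadata(sce)$groundTruth$dox
  expect_gt(mean(call == truth), 0.97)

  zero <- counts
  zero["iTransgene", ] <- 0L
  expect_true(all(!classifyByTransgene(zero)))

  const <- counts
  const["iTransgene", ] <- 7L
  expect_warning(allOn <- classifyByTransgene(const), "degenerate")
  expect_true(all(allOn))
})
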