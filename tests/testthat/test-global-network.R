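# build a GlobalNetwork directly from an edge list (unit-test scaffolding)
toyNetwork <- function(edges, threshold = 0) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new("GlobalNetwork", graph = g, edges = edges,
      centrality = data.frame(), threshold = threshold)
}

test_that("network construction enforces threshold and sign consistency", {
  set.seed(14)
  n <- 60
  base <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("g", 1:5), NULL))
  base[2, ] <- base[1, ] + rnorm(n, 0, 0.4)    # strong positive pair
  base[3, ] <- -base[1, ] + rnorm(n, 0, 0.4)   # strong negative pair
  gn <- buildSpearmanNetwork(base, base + rnorm(length(base), 0, 0.01),
                             threshold = 0.25)
  ed <- networkEdges(gn)
  expect_true(all(abs(ed$weight) > 0.25))
  key <- paste(ed$geneA, ed$geneB)
  expect_true("g1 g2" %in% key)
  expect_true("g1 g3" %in% key)
  expect_gt(ed$weight[key == "g1 g2"], 0)
  expect_lt(ed$weight[key == "g1 g3"], 0)

  # sign conflict between normalizations kills the edge even when the
  # average is large
  mSF <- rbind(a = 1:20 + rnorm(20, 0, 0.1), b = 1:20 + rnorm(20, 0, 0.1))
  mRUV <- rbind(a = mSF["a", ], b = -mSF["b", ])
  expect_identical(nrow(networkEdges(
    buildSpearmanNetwork(mSF, mRUV, 0.25))), 0L)

  expect_error(buildSpearmanNetwork(mSF, mRUV[1, , drop = FALSE]), "gene sets")
})

test_that("centralities match hand-enumerated values on toy graphs", {
  # star K_{1,4}: hub degree 4, betweenness 6 (all leaf pairs); leaves 0
  star <- data.frame(geneA = "hub", geneB = paste0("leaf", 1:4),
                     weight = 1, stringsAsFactors = FALSE)
  ct <- centralityTable(networkCentralities(toyNetwork(star)))
  expect_identical(ct$degree[ct$gene == "hub"], 4L)
  expect_equal(ct$betweenness[ct$gene == "hub"], 6)
  expect_true(all(ct$degree[ct$gene != "hub"] == 1L))
  expect_true(all(ct$betweenness[ct$gene != "hub"] == 0))

  # path a-b-c: betweenness(b) = 1
  path <- data.frame(geneA = c("a", "b"), geneB = c("b", "c"), weight = 1)
  ctp <- centralityTable(networkCentralities(toyNetwork(path)))
  expect_equal(ctp$betweenness[ctp$gene == "b"], 1)
  expect_equal(sum(ctp$betweenness), 1)

  # complete graph with equal weights: eigen centralities all equal (1)
  cmb <- t(combn(paste0("v", 1:5), 2))
  k5 <- data.frame(geneA = cmb[, 1], geneB = cmb[, 2], weight = 0.5)
  ctk <- centralityTable(networkCentralities(toyNetwork(k5)))
  expect_equal(ctk$eigen, rep(1, 5))

  # permuting gene labels permutes centralities identically
  relab <- c(hub = "z9", leaf1 = "a1", leaf2 = "m5", leaf3 = "b2",
             leaf4 = "q7")
  star2 <- data.frame(geneA = relab[star$geneA],
                      geneB = relab[star$geneB], weight = 1,
                      stringsAsFactors = FALSE)
  ct2 <- centralityTable(networkCentralities(toyNetwork(star2)))
  for (g in names(relab)) {
    expect_identical(ct$degree[ct$gene == g],
                     ct2$degree[ct2$gene == relab[[g]]])
    expect_equal(ct$betweenness[ct$gene == g],
                 ct2$betweenness[ct2$gene == relab[[g]]])
  }

  expect_error(networkCentralities(
    toyNetwork(star[0, ])), "empty")
})

test_that("median-split binomial reproduces the worked seed-gene examples", {
  # 101 network genes with distinct centralities: median is the 51st value
  tab <- data.frame(gene = sprintf("g%03d", 1:101), degree = 1:101,
                    betweenness = (1:101) / 2, eigen = (1:101) / 101)
  above <- function(k) {                                 # k genes above
    if (k == 0) character(0) else sprintf("g%03d", 102 - seq_len(k))
  }

  # n = 11, k = 11 -> 2^-11, printed 0.0005
  r11 <- medianSplitBinomial(tab, above(11), "degree")
  expect_equal(r11$pvalue, 2^-11, tolerance = 1e-12)
  expect_equal(round(r11$pvalue, 4), 5e-04)

  # n = 11, k = 10 -> 12/2048, printed 0.006
  r10 <- medianSplitBinomial(tab, c(above(10), "g001"), "degree")
  expect_equal(r10$pvalue, 12 / 2048, tolerance = 1e-12)
  expect_equal(round(r10$pvalue, 3), 0.006)

  # n = 11, k = 9 -> 67/2048, printed 0.03
  r9 <- medianSplitBinomial(tab, c(above(9), "g001", "g002"), "degree")
  expect_equal(r9$pvalue, 67 / 2048, tolerance = 1e-12)
  expect_equal(round(r9$pvalue, 2), 0.03)

  # n = 26, k = 18 -> printed 0.04
  r18 <- medianSplitBinomial(tab, c(above(18), sprintf("g%03d", 1:8)),
                             "degree")
  expect_equal(round(r18$pvalue, 2), 0.04)

  # exact tail equals the exhaustive enumeration oracle for n <= 30
  for (n in c(5, 11, 26, 30)) for (k in c(0, 1, floor(n / 2), n)) {
    enum <- sum(choose(n, k:n)) / 2^n
    lst <- c(above(k), if (k < n) sprintf("g%03d", seq_len(n - k)))
    expect_equal(medianSplitBinomial(tab, lst, "degree")$pvalue, enum,
                 tolerance = 1e-12)
  }

  # ties at the median count as not above
  tied <- data.frame(gene = c("a", "b", "c"), degree = c(1, 2, 3))
  expect_identical(medianSplitBinomial(tied, "b", "degree")$k, 0L)

  expect_error(medianSplitBinomial(tab, "nope", "degree"), "no list gene")
})

test_that("membership Fisher test handles hand-computed and degenerate tables", {
  universe <- paste0("u", 1:8)
  network <- paste0("u", 1:4)
  lst <- c("u1", "u2", "u3", "u5")      # table (3,1; 1,3)
  out <- membershipFisher(network, lst, universe)
  expect_equal(out$pvalue, 0.4857143, tolerance = 1e-6)
  expect_identical(as.vector(out$table), c(3L, 1L, 1L, 3L))

  # list == network == universe: degenerate margins, p = 1
  expect_equal(membershipFisher(universe, universe, universe)$pvalue, 1)

  expect_error(membershipFisher(network, c("u1", "x"), universe), "subset")
  expect_error(membershipFisher(network, lst, character(0)), "empty")

  # independence: p-values roughly uniform across random draws
  set.seed(20)
  ps <- replicate(200, {
    net <- sample(universe, 4)
    l2 <- sample(universe, 4)
    membershipFisher(net, l2, universe)$pvalue
  })
  expect_gt(mean(ps > 0.4), 0.5)   # most mass away from 0 under the null
})
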