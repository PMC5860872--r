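#' Genome-wide Spearman correlation network
#'
#' Computes per-gene-pair Spearman correlations under both normalizations
#' (size factors and spike-in RUV; chips combined into one matrix per
#' normalization beforehand), and keeps an edge only when the two
#' correlations agree in sign and the absolute value of their average
#' exceeds `threshold`. The edge weight is the average correlation;
#' correlations at or below threshold count as "no edge".
#'
#' @param mSF,mRUV gene-by-cell matrices under the two normalizations;
#'   identical gene sets required.
#' @param threshold absolute average-correlation cutoff (default 0.25).
#' @return A [GlobalNetwork-class] object (centrality table empty until
#'   [networkCentralities()] is called).
#' @export
buildSpearmanNetwork <- function(mSF, mRUV, threshold = 0.25) {
  mSF <- as.matrix(mSF)
  mRUV <- as.matrix(mRUV)
  if (!identical(rownames(mSF), rownames(mRUV)))
    stop("gene sets of the two normalizations differ")
  if (!identical(ncol(mSF), ncol(mRUV)))
    stop("cell counts of the two normalizations differ")
  rSF <- suppressWarnings(cor(t(mSF), method = "spearman"))
  rRUV <- suppressWarnings(cor(t(mRUV), method = "spearman"))
  rSF[!is.finite(rSF)] <- 0
  rRUV[!is.finite(rRUV)] <- 0
  avg <- (rSF + rRUV) / 2
  keep <- sign(rSF) == sign(rRUV) & sign(rSF) != 0 & abs(avg) > threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  genes <- rownames(mSF)
  edges <- data.frame(geneA = genes[idx[, 1]], geneB = genes[idx[, 2]],
                      weight = avg[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = unique(c(edges$geneA, edges$geneB))))
  new("GlobalNetwork", graph = g, edges = edges,
      centrality = data.frame(), threshold = threshold)
}

#' Degree, betweenness and eigenvector centrality
#'
#' Degree is the unweighted edge count. Betweenness uses the absolute edge
#' weights directly as path costs (the network's own convention: all
#' relationships made positive, shortest-path counts through each node).
#' Eigenvector centrality is the leading eigenvector of the signed weighted
#' adjacency matrix, computed on the largest connected component, scaled so
#' that its largest absolute score is 1; genes outside that component score
#' 0. An optional `betweennessCost = "one-minus"` flag uses `1 - |w|` as the
#' cost instead.
#'
#' @param gn a [GlobalNetwork-class] object.
#' @param betweennessCost `"abs"` (default) or `"one-minus"`.
#' @return The [GlobalNetwork-class] with its `centrality` slot filled
#'   (`gene`, `degree`, `betweenness`, `eigen`).
#' @export
networkCentralities <- function(gn, betweennessCost = c("abs", "one-minus")) {
  stopifnot(is(gn, "GlobalNetwork"))
  betweennessCost <- match.arg(betweennessCost)
  g <- gn@graph
  if (igraph::ecount(g) == 0) stop("empty network")
  w <- abs(igraph::E(g)$weight)
  cost <- if (betweennessCost == "abs") w else 1 - w
  cost <- pmax(cost, .Machine$double.eps)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = cost)

  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  nodes <- names(comp$membership)[comp$membership == main]
  A <- as.matrix(igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, nodes), attr = "weight", sparse = TRUE))
  ev <- eigen(A, symmetric = TRUE)
  lead <- ev$vectors[, which.max(ev$values)]
  if (lead[which.max(abs(lead))] < 0) lead <- -lead
  lead <- lead / max(abs(lead))
  eig <- setNames(rep(0, length(deg)), names(deg))
  eig[nodes] <- lead

  gn@centrality <- data.frame(gene = names(deg), degree = as.integer(deg),
                              betweenness = as.numeric(btw),
                              eigen = as.numeric(eig),
                              stringsAsFactors = FALSE, row.names = NULL)
  gn
}

#' Median-split binomial enrichment test
#'
#' Counts how many genes of a list have a centrality value strictly above
#' the network-wide median of that measure (by definition 50% of network
#' genes lie above the median) and computes the one-sided exact binomial
#' tail probability `P(X >= k | n, 1/2)`. Ties at the median count as not
#' above.
#'
#' @param centrality centrality table (`data.frame` with a `gene` column and
#'   the measure column), e.g. `centralityTable(gn)`.
#' @param geneList character vector of genes to test.
#' @param measure one of `"degree"`, `"betweenness"`, `"eigen"` (any numeric
#'   column of the table).
#' @return List with `measure`, `n` (list genes present in the network),
#'   `k` (those above the median), `median` and `pvalue`.
#' @examples
#' tab <- data.frame(gene = paste0("g", 1:101), degree = 1:101)
#' medianSplitBinomial(tab, paste0("g", 91:101), "degree")$pvalue # 2^-11
#' @export
medianSplitBinomial <- function(centrality, geneList, measure) {
  stopifnot(is.data.frame(centrality), "gene" %in% names(centrality),
            measure %in% names(centrality))
  vals <- setNames(centrality[[measure]], centrality$gene)
  inNet <- intersect(geneList, centrality$gene)
  if (!length(inNet)) stop("no list gene is present in the network")
  med <- median(vals)
  k <- sum(vals[inNet] > med)
  n <- length(inNet)
  list(measure = measure, n = n, k = k, median = med,
       pvalue = pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Fisher test for network membership of a gene list
#'
#' Two-sided Fisher exact test on the 2x2 table crossing membership in the
#' network against membership in the list, within a stated gene universe.
#'
#' @param networkGenes genes present in the network.
#' @param geneList gene list of interest (subset of `universe`).
#' @param universe the gene universe (e.g. all detected genes).
#' @return List with the 2x2 `table` and the two-sided `pvalue`.
#' @export
membershipFisher <- function(networkGenes, geneList, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(geneList %in% universe))
    stop("gene list is not a subset of the universe")
  networkGenes <- intersect(networkGenes, universe)
  inNet <- universe %in% networkGenes
  inList <- universe %in% geneList
  tab <- table(factor(inNet, c(TRUE, FALSE)), factor(inList, c(TRUE, FALSE)),
               dnn = c("inNetwork", "inList"))
  list(table = tab, pvalue = fisher.test(tab)$p.value)
}
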