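#' Gene lists for lineage averages
#'
#' Hematopoietic and endothelial gene panels whose per-cell mean log2
#' expression summarizes lineage identity in the single-cell qPCR assay.
#'
#' @rdname lineageGenes
#' @export
hematopoieticGenes <- c("Epo", "Epor", "Gata1", "Gata2", "Gfi1", "Gfi1b",
                        "Hbb-bh1", "Itga2b", "Itgam", "Itgb3", "Kit", "Lmo2",
                        "Lyl1", "Mpo", "Myb", "Ptprc", "Runx1", "Sfpi1",
                        "Sla", "Tal1", "Thpo")

#' @rdname lineageGenes
#' @export
endothelialGenes <- c("Cdh5", "Cldn5", "Eng", "Esam", "Fbn1", "Gpr126",
                      "Kdr", "Npr1", "Pcdh12", "Pecam1", "Ptprb", "Ptprm",
                      "Ramp2", "Sox7", "Tek")

#' Convert Ct values to log2 expression with a limit of detection
#'
#' Implements the limit-of-detection conversion `log2ex = LOD - Ct` for
#' `Ct < LOD` and 0 otherwise. Failed reactions (mask or `NA`) map to 0,
#' consistent with "not detected".
#'
#' @param ct numeric cell-by-gene matrix of Ct values.
#' @param lod limit of detection in cycles; the default 24 corresponds to a
#'   single input copy on the microfluidic qPCR platform.
#' @param mask optional logical matrix marking failed reactions (`TRUE` =
#'   failed).
#' @return Matrix of the same shape with values in `[0, lod]` ("Log2 Gene
#'   Expression").
#' @examples
#' ctToLog2Ex(matrix(c(20, 24, 30), 1), lod = 24)  # 4 0 0
#' @export
ctToLog2Ex <- function(ct, lod = 24, mask = NULL) {
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0)
    stop("lod must be a single positive number")
  ct <- as.matrix(ct)
  out <- ifelse(!is.na(ct) & ct < lod, lod - ct, 0)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(ct)))
    out[mask] <- 0
  }
  dimnames(out) <- dimnames(ct)
  out
}

#' Per-cell hematopoietic and endothelial expression averages
#'
#' @param x cell-by-gene log2-expression matrix (see [ctToLog2Ex()]).
#' @param hemaGenes,endoGenes gene panels to average; defaults are the
#'   shipped [hematopoieticGenes] and [endothelialGenes] lists.
#' @return `data.frame` with per-cell `hemaAvg` and `endoAvg`.
#' @export
lineageScores <- function(x, hemaGenes = hematopoieticGenes,
                          endoGenes = endothelialGenes) {
  x <- as.matrix(x)
  missing <- setdiff(c(hemaGenes, endoGenes), colnames(x))
  if (length(missing))
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  data.frame(hemaAvg = rowMeans(x[, hemaGenes, drop = FALSE]),
             endoAvg = rowMeans(x[, endoGenes, drop = FALSE]),
             row.names = rownames(x))
}

#' Hierarchically cluster cells of a log2-expression matrix
#'
#' Cells are clustered by normalized Euclidean distance (Euclidean distance
#' divided by the number of genes, an average fold-change scale) with
#' complete linkage, and the tree is cut into `k` clusters. Genes are
#' ordered by complete linkage on one minus their Pearson correlation. A
#' global z-score transform of the matrix is returned for display-style
#' export.
#'
#' @param x cell-by-gene numeric matrix.
#' @param k requested number of cell clusters (the reproducible counterpart
#'   of cutting a dendrogram at a drawn height).
#' @return List with `labels` (named integer cluster per cell), `cellTree`
#'   and `geneTree` (`hclust` objects), `geneOrder`, `globalZ`, and `k`.
#' @export
clusterCells <- function(x, k) {
  x <- as.matrix(x)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of cells (",
                        nrow(x), ")")
  d <- dist(x) / ncol(x)
  cellTree <- hclust(d, method = "complete")
  labels <- cutree(cellTree, k = k)
  geneCor <- suppressWarnings(cor(x))
  geneCor[!is.finite(geneCor)] <- 0
  geneTree <- hclust(as.dist(1 - geneCor), method = "complete")
  globalZ <- (x - mean(x)) / sd(x)
  list(labels = labels, cellTree = cellTree, geneTree = geneTree,
       geneOrder = geneTree$order, globalZ = globalZ, k = k)
}

#' Cluster prototypes and their correlation
#'
#' The prototype of a cluster is the per-gene mean over its member cells;
#' prototypes are compared by Pearson correlation.
#'
#' @param x cell-by-gene numeric matrix.
#' @param labels cluster assignment per cell (vector aligned with rows of
#'   `x`), e.g. `clusterCells(x, k)$labels`.
#' @return List with `prototypes` (cluster-by-gene matrix) and `correlation`
#'   (symmetric unit-diagonal Pearson matrix).
#' @export
clusterPrototypes <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty cluster in labels")
  protos <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  rownames(protos) <- levels(labels)
  list(prototypes = protos, correlation = cor(t(protos)))
}

#' Principal component analysis with a deterministic sign convention
#'
#' Centered (unscaled) PCA. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms; zero-variance components are flagged.
#'
#' @param x observation-by-variable numeric matrix.
#' @param nComponents number of components to return.
#' @return List with `scores`, `loadings`, `varExplained` (fraction per
#'   component) and `zeroVariance` (logical per component).
#' @export
pcaScores <- function(x, nComponents = 2L) {
  x <- as.matrix(x)
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds min(dim(x))")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  nComponents <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  sco <- pc$x[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  tot <- sum(pc$sdev^2)
  varExplained <- if (tot > 0) pc$sdev[seq_len(nComponents)]^2 / tot
                  else rep(0, nComponents)
  list(scores = sco, loadings = rot, varExplained = varExplained,
       zeroVariance = pc$sdev[seq_len(nComponents)]^2 < .Machine$double.eps)
}
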