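#' Median-of-ratios size factors
#'
#' DESeq-style size factors: the size factor of a cell is the median, over
#' genes with a finite log geometric mean, of the ratio between the cell's
#' count and that geometric mean. When no gene is expressed in every cell
#' (common for sparse single-cell data), the geometric mean is computed over
#' positive counts only and a warning is emitted.
#'
#' @param counts gene-by-cell count matrix.
#' @return Positive numeric vector of per-cell size factors (named by cell).
#' @seealso [sfNormalize()]
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  logc <- log(counts)
  logGeo <- rowMeans(logc)           # -Inf for genes with any zero
  usable <- is.finite(logGeo)
  if (!any(usable)) {
    warning("no gene expressed in all cells; ",
            "using positive-count geometric means")
    logGeo <- apply(logc, 1, function(r) {
      f <- is.finite(r)
      if (any(f)) mean(r[f]) else -Inf
    })
    usable <- is.finite(logGeo)
    if (!any(usable)) stop("all-zero count matrix")
  }
  sf <- apply(logc, 2, function(cc) {
    r <- (cc - logGeo)[usable & is.finite(cc)]
    if (!length(r)) stop("a cell shares no positive gene with the reference")
    exp(median(r))
  })
  setNames(sf, colnames(counts))
}

#' Size-factor-normalized counts
#'
#' @param counts gene-by-cell count matrix.
#' @return List with `normalized` (counts divided cell-wise by size factors)
#'   and `sizeFactors`.
#' @export
sfNormalize <- function(counts) {
  sf <- computeSizeFactors(counts)
  list(normalized = sweep(as.matrix(counts), 2, sf, "/"), sizeFactors = sf)
}

#' Spike-in-based removal of unwanted variation (RUVg-style)
#'
#' On `log(count + 1)`, estimates `k` unwanted factors as the leading right
#' singular vectors of the row-centered control-gene (spike-in) submatrix
#' and regresses them out of every gene, preserving gene means. Control
#' genes are assumed to carry technical but no biological variation, so the
#' removed directions capture unwanted cell-level effects.
#'
#' @param counts gene-by-cell count matrix.
#' @param controlGenes names (or indices) of the control genes.
#' @param k number of unwanted factors (must be >= 1 and smaller than the
#'   number of control genes).
#' @return List with `adjusted` (log-scale gene-by-cell matrix), `factors`
#'   (cell-by-k matrix of unwanted-factor scores) and `k`.
#' @export
ruvNormalize <- function(counts, controlGenes, k = 1L) {
  counts <- as.matrix(counts)
  if (k < 1) stop("k must be at least 1")
  if (is.character(controlGenes)) {
    missing <- setdiff(controlGenes, rownames(counts))
    if (length(missing))
      stop("control genes absent: ", paste(missing, collapse = ", "))
  }
  ctrl <- counts[controlGenes, , drop = FALSE]
  if (nrow(ctrl) < k + 1)
    stop("need at least k + 1 control genes")
  y <- log(counts + 1)
  yc <- y - rowMeans(y)
  ctrlC <- yc[rownames(ctrl), , drop = FALSE]
  sv <- svd(ctrlC, nu = 0, nv = k)
  if (sum(sv$d > 1e-12) < k)
    stop("k exceeds the rank of the centered control-gene matrix")
  W <- sv$v[, seq_len(k), drop = FALSE]          # cells x k, orthonormal
  adjusted <- y - (yc %*% W) %*% t(W)
  rownames(W) <- colnames(counts)
  list(adjusted = adjusted, factors = W, k = k)
}

#' Highly variable gene selection and PCA
#'
#' Fits a smooth mean-variance trend (loess of log variance on log mean,
#' span 0.3) across genes, ranks genes by their variance above the trend,
#' and runs a centered PCA on the `nTop` top-ranked genes. Ties (and genes
#' without a defined residual) are broken lexicographically by gene name, so
#' selection is deterministic.
#'
#' @param m gene-by-cell numeric matrix (normalized expression).
#' @param nTop number of genes to keep (default 400).
#' @param nPc number of principal components to return.
#' @param span loess span for the trend fit.
#' @return List with `genes` (selected, length exactly `nTop`), `residuals`
#'   (trend-corrected log variance per gene) and the [pcaScores()] output
#'   (`scores`, `loadings`, `varExplained`).
#' @export
hvgPca <- function(m, nTop = 400L, nPc = 2L, span = 0.3) {
  m <- as.matrix(m)
  if (nTop > nrow(m)) stop("nTop exceeds the number of genes")
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  ok <- v > 0 & mu > 0
  resid <- setNames(rep(-Inf, nrow(m)), rownames(m))
  if (sum(ok) >= 4) {
    df <- data.frame(lm = log(mu[ok]), lv = log(v[ok]))
    fit <- loess(lv ~ lm, data = df, span = span, degree = 2)
    resid[ok] <- df$lv - predict(fit)
  } else if (any(ok)) {
    resid[ok] <- log(v[ok])
  }
  ord <- order(-resid, rownames(m))
  genes <- rownames(m)[ord[seq_len(nTop)]]
  pca <- pcaScores(t(m[genes, , drop = FALSE]), nPc)
  c(list(genes = genes, residuals = resid), pca)
}
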