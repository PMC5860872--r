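#' Write a count matrix as MatrixMarket plus sidecars
#'
#' Writes `matrix.mtx` (1-based MatrixMarket coordinates), `genes.tsv`
#' (gene, role, and any further `rowData` columns) and `cells.tsv` (cell and
#' `colData` columns) into `dir`, together with `metadata.json` carrying
#' provenance (dimensions and parameters).
#'
#' @param sce a `SingleCellExperiment` (or a plain gene-by-cell matrix, in
#'   which case all roles are `"endogenous"`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountMatrix <- function(sce, dir) {
  if (is.matrix(sce) || is(sce, "Matrix")) {
    sce <- SingleCellExperiment(
      assays = list(counts = sce),
      rowData = DataFrame(role = rep("endogenous", nrow(sce)),
                          row.names = rownames(sce)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- assay(sce, "counts")
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  gd <- as.data.frame(rowData(sce))
  gd <- cbind(gene = rownames(sce), gd)
  write.table(gd, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cd <- as.data.frame(colData(sce))
  cd <- cbind(cell = colnames(sce), cd)
  write.table(cd, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(nGenes = nrow(sce), nCells = ncol(sce),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a count matrix written by [writeCountMatrix()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return A `SingleCellExperiment` with assay `"counts"`.
#' @export
readCountMatrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
    stop("sidecar dimensions do not match the matrix (",
         nrow(genes), " genes, ", nrow(cells), " cells vs ",
         nrow(m), " x ", ncol(m), ")")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes$gene, cells$cell)
  rd <- genes[, setdiff(names(genes), "gene"), drop = FALSE]
  cd <- cells[, setdiff(names(cells), "cell"), drop = FALSE]
  SingleCellExperiment(
    assays = list(counts = m),
    rowData = DataFrame(rd, row.names = genes$gene),
    colData = DataFrame(cd, row.names = cells$cell))
}

#' Read/write read-record tables
#'
#' Four-column TSV (`well_barcode`, `umi`, `gene`, `reads`); extra columns
#' are preserved.
#'
#' @param records record table (`data.frame`/`data.table`).
#' @param path TSV file path.
#' @return `readReadRecords` returns a `data.table`.
#' @rdname readRecordsIO
#' @export
writeReadRecords <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t")
  invisible(path)
}

#' @rdname readRecordsIO
#' @export
readReadRecords <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("well_barcode", "umi", "gene", "reads")
  if (!all(need %in% names(dt)))
    stop("record file must have columns ", paste(need, collapse = ", "))
  if (any(dt$reads < 1)) stop("read counts must be >= 1")
  dt
}

#' Write a seed-network edge list as TSV
#'
#' @param net a [SeedNetwork-class] or a consensus edge `data.frame`.
#' @param path TSV file path.
#' @export
writeEdgeList <- function(net, path) {
  if (is(net, "SeedNetwork")) net <- seedEdges(net)
  write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
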