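# integer encoding of equal-length DNA strings; rows = positions
.encodeDna <- function(x) {
  n <- length(x)
  if (n == 0) return(matrix(integer(0), 0, 0))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("sequences must have equal length")
  vapply(x, utf8ToInt, integer(lens[1]))  # len x n
}

# one-hot encoding over positions x {A,C,G,T}; 'N' (or any other byte)
# encodes as all-zero and therefore mismatches everything, including 'N'
.onehotDna <- function(x) {
  e <- .encodeDna(x)                      # len x n
  L <- nrow(e)
  n <- ncol(e)
  base <- match(e, c(65L, 67L, 71L, 84L))  # A,C,G,T byte codes; NA for N etc.
  out <- matrix(0, n, 4L * L)
  pos <- rep(seq_len(L), n)
  ok <- !is.na(base)
  out[cbind(rep(seq_len(n), each = L)[ok], (pos[ok] - 1L) * 4L + base[ok])] <- 1
  out
}

# Hamming distances between two sets of equal-length strings ('N' bases
# count as mismatches to every base)
.hammingMatrix <- function(a, b = a) {
  if (length(unique(nchar(c(a, b)))) != 1L)
    stop("sequences must have equal length")
  L <- nchar(a[1])
  d <- L - tcrossprod(.onehotDna(a), .onehotDna(b))
  dimnames(d) <- list(a, b)
  d
}

#' Assign read records to wells by barcode matching
#'
#' Each record is assigned to the whitelist barcode nearest in Hamming
#' distance, tolerating up to `maxMismatch` mismatches; a record is
#' discarded as ambiguous when the minimum distance is achieved by more than
#' one whitelist entry, and as unassigned when no entry is within tolerance.
#' `N` bases mismatch every base.
#'
#' @param records `data.table`/`data.frame` with at least columns
#'   `well_barcode`, `umi`, `gene`, `reads`.
#' @param whitelist character vector of known well barcodes (equal length).
#' @param maxMismatch maximum tolerated mismatches (default 2).
#' @return List with `records` (assigned records; `well_barcode` replaced by
#'   the matched whitelist entry) and `discarded` (number of read-group
#'   records dropped).
#' @export
assignWells <- function(records, whitelist, maxMismatch = 2L) {
  if (!length(whitelist)) stop("whitelist is empty")
  if (length(unique(nchar(whitelist))) != 1L)
    stop("whitelist barcodes must have equal length")
  dt <- as.data.table(records)
  obs <- unique(dt$well_barcode)
  if (length(unique(nchar(obs))) > 1L ||
      nchar(obs[1]) != nchar(whitelist[1]))
    stop("record barcodes must match the whitelist barcode length")
  d <- .hammingMatrix(obs, whitelist)
  dmin <- apply(d, 1, min)
  nBest <- rowSums(d == dmin)
  ok <- dmin <= maxMismatch & nBest == 1L
  match <- whitelist[apply(d, 1, which.min)]
  map <- ifelse(ok, match, NA_character_)
  names(map) <- obs
  assigned <- unname(map[dt$well_barcode])
  keep <- !is.na(assigned)
  discarded <- sum(!keep)
  dt <- dt[keep]
  dt[, well_barcode := assigned[keep]]
  list(records = dt, discarded = discarded)
}

#' Iterative UMI error correction
#'
#' Collapses sequencing-error UMI satellites into their parent barcode.
#' Anchors are processed in decreasing order of read support (ties broken
#' lexicographically). For the current anchor, every not-yet-considered UMI
#' within `maxMismatch` Hamming distance whose read count is below
#' `minorFraction` of the anchor's current total is merged into the anchor
#' (reads added); merging re-evaluates candidates against the anchor's
#' updated total until no further UMI qualifies. Anchor and merged UMIs are
#' then marked as considered and the procedure restarts with the
#' highest-support unconsidered UMI until none is left. Total reads are
#' conserved.
#'
#' @param umiCounts named numeric vector mapping UMI to read count.
#' @param maxMismatch Hamming radius for "similar" barcodes (default 2).
#' @param minorFraction merge threshold: a UMI is corrected only if its
#'   reads are strictly less than this fraction of the anchor's (default
#'   0.10).
#' @return Named numeric vector of corrected UMI read counts.
#' @examples
#' correctUmis(c(AAAA = 100, AAAT = 5, CCCC = 50))  # AAAT merged into AAAA
#' @export
correctUmis <- function(umiCounts, maxMismatch = 2L, minorFraction = 0.10) {
  if (length(umiCounts) == 0) return(umiCounts)
  if (any(umiCounts <= 0)) stop("read counts must be positive")
  k <- length(umiCounts)
  if (k == 1L) return(umiCounts)

  umis <- names(umiCounts)
  reads <- as.numeric(umiCounts)
  d <- .hammingMatrix(umis)
  considered <- rep(FALSE, k)
  out <- reads

  # anchors in decreasing read support, lexicographic on ties; a UMI that is
  # not yet considered has never received merged reads, so the original
  # ordering is the current one
  for (anchor in order(-reads, umis)) {
    if (considered[anchor]) next
    repeat {
      cand <- which(!considered & d[anchor, ] <= maxMismatch &
                    out < minorFraction * out[anchor])
      cand <- cand[cand != anchor]
      if (!length(cand)) break
      out[anchor] <- out[anchor] + sum(out[cand])
      out[cand] <- 0
      considered[cand] <- TRUE
    }
    considered[anchor] <- TRUE
  }
  kept <- out > 0
  setNames(out[kept], umis[kept])
}

#' Drop weakly supported UMIs
#'
#' Removes UMIs supported by fewer than `minReads` reads (by default, UMIs
#' with only one or two reads are omitted from counting).
#'
#' @param umiCounts named numeric vector of (corrected) UMI read counts.
#' @param minReads minimum read support (default 3).
#' @return Filtered named vector.
#' @export
filterUmis <- function(umiCounts, minReads = 3L) {
  umiCounts[umiCounts >= minReads]
}

#' Build a UMI count matrix from well-assigned read records
#'
#' For every (cell, gene) the UMI read counts are error-corrected with
#' [correctUmis()], filtered with [filterUmis()], and the surviving distinct
#' UMIs are counted ("UMIs per gene").
#'
#' @param records well-assigned records (see [assignWells()]) with columns
#'   `well_barcode`, `umi`, `gene`, `reads`.
#' @param maxMismatch,minorFraction passed to [correctUmis()].
#' @param minReads passed to [filterUmis()].
#' @return Integer gene-by-cell matrix of molecule counts (cells keyed by
#'   well barcode).
#' @export
umiCountMatrix <- function(records, maxMismatch = 2L, minorFraction = 0.10,
                           minReads = 3L) {
  dt <- as.data.table(records)[, .(reads = sum(reads)),
                               by = .(well_barcode, gene, umi)]
  counted <- dt[, {
    v <- setNames(as.numeric(reads), umi)
    v <- filterUmis(correctUmis(v, maxMismatch, minorFraction), minReads)
    .(n = length(v))
  }, by = .(well_barcode, gene)]
  counted <- counted[n > 0L]
  genes <- sort(unique(counted$gene))
  cells <- sort(unique(dt$well_barcode))
  m <- matrix(0L, length(genes), length(cells),
              dimnames = list(genes, cells))
  m[cbind(match(counted$gene, genes),
          match(counted$well_barcode, cells))] <- as.integer(counted$n)
  m
}

#' Sparseness quality filter for UMI count matrices
#'
#' Removes cells detecting fewer than `minGenesPerCell` genes (at least one
#' UMI), then genes detected in fewer than `minCellsPerGene` of the
#' remaining cells. Cells are filtered before genes.
#'
#' @param m gene-by-cell count matrix.
#' @param minGenesPerCell minimum detected genes per retained cell
#'   (default 1000).
#' @param minCellsPerGene minimum cells per retained gene (default 10).
#' @return Filtered matrix; attributes `removedCells` and `removedGenes`
#'   record the dropped names.
#' @export
qcFilter <- function(m, minGenesPerCell = 1000L, minCellsPerGene = 10L) {
  m <- as.matrix(m)
  keepCells <- colSums(m > 0) >= minGenesPerCell
  m2 <- m[, keepCells, drop = FALSE]
  keepGenes <- rowSums(m2 > 0) >= minCellsPerGene
  out <- m2[keepGenes, , drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0)
    stop("QC filter removed everything (", sum(!keepCells), " cells below ",
         minGenesPerCell, " genes; ", sum(!keepGenes), " genes below ",
         minCellsPerGene, " cells)")
  attr(out, "removedCells") <- colnames(m)[!keepCells]
  attr(out, "removedGenes") <- rownames(m2)[!keepGenes]
  out
}

#' Microfluidic (C1-style) cell quality filter
#'
#' Excludes wells with fewer than `minReads` total reads (deemed empty),
#' cells with an rRNA read fraction above `maxRrnaFraction`, and cells that
#' are outliers on the first principal component of size-factor-normalized
#' log counts (|PC1 score| more than `madThreshold` median absolute
#' deviations from the median).
#'
#' @param readsPerWell named numeric vector of total reads per well.
#' @param rrnaFraction named numeric vector of rRNA read fractions.
#' @param counts gene-by-cell count matrix (endogenous genes) used for the
#'   PC1 outlier screen.
#' @param minReads minimum reads per well (default 1e6).
#' @param maxRrnaFraction maximum rRNA fraction (default 0.07).
#' @param madThreshold PC1 outlier cutoff in MADs (default 3).
#' @return List with `kept` (cell names), `removed` (named character vector
#'   of reasons) and `detectedGenes` (per kept cell).
#' @export
qcFilterC1 <- function(readsPerWell, rrnaFraction, counts,
                       minReads = 1e6, maxRrnaFraction = 0.07,
                       madThreshold = 3) {
  counts <- as.matrix(counts)
  cells <- colnames(counts)
  stopifnot(!is.null(cells), all(cells %in% names(readsPerWell)),
            all(cells %in% names(rrnaFraction)))
  reason <- setNames(rep(NA_character_, length(cells)), cells)
  reason[readsPerWell[cells] < minReads] <- "low_reads"
  reason[is.na(reason) & rrnaFraction[cells] > maxRrnaFraction] <- "rRNA"

  pool <- cells[is.na(reason)]
  if (length(pool) >= 4) {
    sf <- computeSizeFactors(counts[, pool, drop = FALSE])
    lg <- log2(sweep(counts[, pool, drop = FALSE], 2, sf, "/") + 1)
    pc1 <- pcaScores(t(lg), 1L)$scores[, 1]
    dev <- abs(pc1 - median(pc1))
    cut <- madThreshold * mad(pc1)
    if (cut > 0) reason[pool[dev > cut]] <- "pc1_outlier"
  }
  kept <- cells[is.na(reason)]
  list(kept = kept, removed = reason[!is.na(reason)],
       detectedGenes = colSums(counts[, kept, drop = FALSE] > 0))
}
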