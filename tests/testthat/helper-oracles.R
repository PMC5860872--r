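# Independent oracle implementations, deliberately written along different
# algebraic routes than the package internals.

# Distance correlation via the triple-sum identity V^2 = S1 - 2 S2 + S3.
oracleDcor <- function(x, y) {
  n <- length(x)
  a <- as.matrix(dist(x))
  b <- as.matrix(dist(y))
  v2 <- function(a, b) {
    S1 <- mean(a * b)
    S2 <- sum(rowSums(a) * rowSums(b)) / n^3
    S3 <- mean(a) * mean(b)
    S1 - 2 * S2 + S3
  }
  vxy <- v2(a, b)
  den <- sqrt(v2(a, a) * v2(b, b))
  if (den <= .Machine$double.eps) return(0)
  sqrt(max(vxy, 0) / den)
}

# U-centering written element-wise (loops), for the pdcor oracle.
oracleUcenter <- function(d) {
  n <- nrow(d)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[i, j] <- d[i, j] - sum(d[i, ]) / (n - 2) - sum(d[, j]) / (n - 2) +
      sum(d) / ((n - 1) * (n - 2))
  }
  out
}

# Partial distance correlation via explicit Hilbert-space projection.
oraclePdcor <- function(x, y, z) {
  n <- length(x)
  A <- oracleUcenter(as.matrix(dist(x)))
  B <- oracleUcenter(as.matrix(dist(y)))
  C <- oracleUcenter(as.matrix(dist(z)))
  ip <- function(u, v) sum(u * v) / (n * (n - 3))
  proj <- function(u, v) {           # residual of u after projecting on v
    vv <- ip(v, v)
    if (vv <= .Machine$double.eps) u else u - (ip(u, v) / vv) * v
  }
  Pa <- proj(A, C)
  Pb <- proj(B, C)
  den <- sqrt(ip(Pa, Pa) * ip(Pb, Pb))
  if (!is.finite(den) || den <= .Machine$double.eps) return(0)
  ip(Pa, Pb) / den
}

# Literal re-statement of the iterative UMI correction procedure, kept
# structurally different from the package version (explicit queue of
# unconsidered barcodes, string-wise Hamming).
oracleCorrectUmis <- function(counts, maxMismatch = 2L,
                              minorFraction = 0.10) {
  hamming <- function(a, b) {
    sa <- strsplit(a, "")[[1]]
    sb <- strsplit(b, "")[[1]]
    sum(sa != sb | sa == "N" | sb == "N")
  }
  pending <- names(counts)
  total <- as.numeric(counts)
  names(total) <- names(counts)
  repeat {
    if (!length(pending)) break
    ord <- pending[order(-total[pending], pending)]
    anchor <- ord[1]
    repeat {
      merged <- FALSE
      for (u in setdiff(pending, anchor)) {
        if (hamming(u, anchor) <= maxMismatch &&
            total[u] < minorFraction * total[anchor]) {
          total[anchor] <- total[anchor] + total[u]
          total[u] <- 0
          pending <- setdiff(pending, u)
          merged <- TRUE
        }
      }
      if (!merged) break
    }
    pending <- setdiff(pending, anchor)
  }
  total[total > 0]
}

randomUmiCounts <- function(k, len = 4L) {
  umis <- unique(replicate(k, paste0(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  setNames(sample(c(1:5, 10, 50, 100, 200), length(umis), replace = TRUE),
           umis)
}
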