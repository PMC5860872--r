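#' Seed-to-transcriptome distance-correlation screen
#'
#' For one configuration (one chip under one normalization), computes the
#' distance correlation between every seed gene and every other gene,
#' attaches a permutation p-value (the seed's values are permuted; the
#' double-centered distance matrices are re-used, so permutations are
#' exact re-computations), applies Benjamini-Hochberg adjustment across all
#' seed-gene pairs of the configuration, and labels the direction of each
#' relationship from a two-tailed t-test on the Pearson correlation
#' coefficient: the sign of `r` when `p <= directionAlpha`, `"other"`
#' otherwise.
#'
#' @param m gene-by-cell numeric matrix (normalized expression).
#' @param seeds seed gene names (must be rows of `m`).
#' @param alpha significance level applied to (adjusted) dcor p-values.
#' @param nPerm number of permutations.
#' @param rngSeed integer seed for the permutations.
#' @param configId label identifying the configuration (chip x
#'   normalization), carried into [consensusEdges()].
#' @param adjust `"BH"` (default) or `"none"` for the dcor p-values.
#' @param directionAlpha uncorrected threshold of the direction t-test.
#' @return `data.frame` with columns `seed`, `target`, `dcor`, `pvalue`,
#'   `padj`, `significant`, `direction`, `config`.
#' @export
findSeedTargets <- function(m, seeds, alpha = 0.05, nPerm = 499L,
                            rngSeed = 1L, configId = "config1",
                            adjust = c("BH", "none"),
                            directionAlpha = 0.05) {
  adjust <- match.arg(adjust)
  m <- as.matrix(m)
  missing <- setdiff(seeds, rownames(m))
  if (length(missing))
    stop("seed genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  n <- ncol(m)
  if (n < 4) stop("need at least 4 cells")
  S <- length(seeds)
  genes <- rownames(m)
  G <- length(genes)

  set.seed(rngSeed)
  # flattened double-centered distance matrices of the seeds (n^2 x S)
  Amat <- vapply(seeds, function(s) as.vector(.dcenter(.distMat(m[s, ]))),
                 numeric(n * n))
  dvarA <- colSums(Amat * Amat) / (n * n)

  perms <- replicate(nPerm, sample.int(n), simplify = FALSE)
  permIdx <- lapply(perms, function(p) rep((p - 1L) * n, each = n) + p)

  blockSize <- max(1L, floor(6e6 / (n * n)))
  blocks <- split(seq_len(G), ceiling(seq_len(G) / blockSize))

  dcorMat <- matrix(0, S, G, dimnames = list(seeds, genes))
  pMat <- matrix(1, S, G, dimnames = list(seeds, genes))
  for (bl in blocks) {
    Bmat <- vapply(bl, function(g) as.vector(.dcenter(.distMat(m[g, ]))),
                   numeric(n * n))
    dvarB <- colSums(Bmat * Bmat) / (n * n)
    obs <- crossprod(Amat, Bmat) / (n * n)        # S x |bl| dcov^2
    counts <- matrix(0L, S, length(bl))
    for (idx in permIdx) {
      permStat <- crossprod(Amat[idx, , drop = FALSE], Bmat) / (n * n)
      counts <- counts + (permStat >= obs)
    }
    den <- sqrt(outer(dvarA, dvarB))
    dc <- matrix(0, S, length(bl))
    okDen <- den > .Machine$double.eps
    dc[okDen] <- sqrt(pmax(obs[okDen] / den[okDen], 0))
    p <- (1 + counts) / (nPerm + 1)
    p[!okDen] <- 1
    dcorMat[, bl] <- dc
    pMat[, bl] <- p
  }

  # direction: two-tailed t-test on the Pearson correlation
  r <- suppressWarnings(cor(t(m[seeds, , drop = FALSE]), t(m)))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pDir <- 2 * pt(-abs(tstat), df = n - 2)

  res <- data.frame(
    seed = rep(seeds, G),
    target = rep(genes, each = S),
    dcor = as.vector(dcorMat),
    pvalue = as.vector(pMat),
    direction = ifelse(as.vector(pDir) <= directionAlpha,
                       ifelse(as.vector(r) > 0, "positive", "negative"),
                       "other"),
    stringsAsFactors = FALSE)
  res <- res[res$seed != res$target, ]
  res$padj <- if (adjust == "BH") bhAdjust(res$pvalue) else res$pvalue
  res$significant <- res$padj < alpha
  res$config <- configId
  rownames(res) <- NULL
  res[, c("seed", "target", "dcor", "pvalue", "padj", "significant",
          "direction", "config")]
}

#' Cross-configuration consensus of seed-target relationships
#'
#' A relationship is retained only when it is significant in at least
#' `minConfigs` configurations; its direction is the common label when all
#' supporting configurations agree and `"other"` otherwise (conflicting
#' directionalities collapse to `"other"`).
#'
#' @param results `data.frame` combining [findSeedTargets()] outputs over
#'   configurations (rows bound together).
#' @param minConfigs minimum number of supporting configurations
#'   (default 2).
#' @param expectedConfigs optional character vector; an error is raised if
#'   `results$config` contains anything else.
#' @return `data.frame` with columns `seed`, `target`, `direction`,
#'   `nConfigs`, `meanDcor`.
#' @export
consensusEdges <- function(results, minConfigs = 2L,
                           expectedConfigs = NULL) {
  stopifnot(all(c("seed", "target", "significant", "direction",
                  "config") %in% names(results)))
  if (!is.null(expectedConfigs)) {
    bad <- setdiff(unique(results$config), expectedConfigs)
    if (length(bad))
      stop("unknown configuration id: ", paste(bad, collapse = ", "))
  }
  sig <- as.data.table(results)[significant == TRUE]
  if (nrow(sig) == 0)
    return(data.frame(seed = character(), target = character(),
                      direction = character(), nConfigs = integer(),
                      meanDcor = numeric(), stringsAsFactors = FALSE))
  cons <- sig[, {
    dirs <- unique(direction)
    .(direction = if (length(dirs) == 1L) dirs else "other",
      nConfigs = length(unique(config)), meanDcor = mean(dcor))
  }, by = .(seed, target)]
  out <- as.data.frame(cons[nConfigs >= minConfigs])
  out[order(out$seed, out$target), , drop = FALSE]
}

# bias-corrected dcor matrix (and optionally V-statistic dcor matrix) for a
# set of genes, from one crossprod of flattened centered distance matrices
.pairwiseDcorMats <- function(m, genes, withVstat = FALSE) {
  n <- ncol(m)
  U <- vapply(genes, function(g) as.vector(.ucenter(.distMat(m[g, ]))),
              numeric(n * n))
  gram <- crossprod(U) / (n * (n - 3))
  d <- diag(gram)
  den <- sqrt(outer(d, d))
  R <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  ok <- den > .Machine$double.eps
  R[ok] <- gram[ok] / den[ok]
  diag(R) <- 1
  out <- list(R = R)
  if (withVstat) {
    Dv <- vapply(genes, function(g) as.vector(.dcenter(.distMat(m[g, ]))),
                 numeric(n * n))
    gv <- crossprod(Dv) / (n * n)
    dv <- diag(gv)
    denv <- sqrt(outer(dv, dv))
    DC <- matrix(0, length(genes), length(genes),
                 dimnames = list(genes, genes))
    okv <- denv > .Machine$double.eps
    DC[okv] <- sqrt(pmax(gv[okv] / denv[okv], 0))
    out$dcor <- DC
  }
  out
}

#' Infer seed-seed interactions by partial distance correlation
#'
#' For every seed pair (s1, s2) and every retained target g of either seed,
#' the strength of the seed-target relationship conditioned on the other
#' seed (`pdcor(s, g; other)`) is compared with its unconditional strength.
#' An interaction is inferred when both conditioned relationships strictly
#' increase (beyond `margin`) for at least one common target, in at least
#' `minConfigs` configurations. By default the unconditional baseline is the
#' bias-corrected distance correlation (`baseline = "bcdcor"`), the same
#' U-statistic scale as pdcor; `baseline = "dcor"` compares against the
#' plain distance correlation instead.
#'
#' @param matrices named list of gene-by-cell matrices, one per
#'   configuration (names are configuration ids).
#' @param edges consensus edge table from [consensusEdges()].
#' @param seeds seed gene names.
#' @param minConfigs consensus threshold (default 2).
#' @param margin required strict increase (default 0).
#' @param baseline `"bcdcor"` (default) or `"dcor"`.
#' @return `data.frame` with columns `seed1`, `seed2`, `nConfigs`,
#'   `targets` (comma-separated supporting targets, union over supporting
#'   configurations).
#' @export
inferSeedInteractions <- function(matrices, edges, seeds,
                                  minConfigs = 2L, margin = 0,
                                  baseline = c("bcdcor", "dcor")) {
  baseline <- match.arg(baseline)
  if (nrow(edges) == 0 || length(seeds) < 2) return(emptyInteractions())
  targets <- setdiff(unique(edges$target), seeds)
  pairs <- t(utils::combn(sort(seeds), 2))

  perConfig <- lapply(names(matrices), function(cfg) {
    m <- as.matrix(matrices[[cfg]])
    genes <- intersect(c(seeds, targets), rownames(m))
    mats <- .pairwiseDcorMats(m, genes, withVstat = baseline == "dcor")
    R <- mats$R
    base <- if (baseline == "dcor") mats$dcor else R
    hits <- list()
    for (i in seq_len(nrow(pairs))) {
      s1 <- pairs[i, 1]; s2 <- pairs[i, 2]
      if (!(s1 %in% genes && s2 %in% genes)) next
      tg <- intersect(
        unique(edges$target[edges$seed %in% c(s1, s2)]),
        setdiff(genes, c(s1, s2)))
      if (!length(tg)) next
      r12 <- R[s1, s2]
      d1 <- sqrt(pmax((1 - r12^2) * (1 - R[tg, s2]^2), 0))
      d2 <- sqrt(pmax((1 - r12^2) * (1 - R[tg, s1]^2), 0))
      pd1 <- ifelse(d1 > .Machine$double.eps,
                    (R[s1, tg] - r12 * R[tg, s2]) / d1, 0)
      pd2 <- ifelse(d2 > .Machine$double.eps,
                    (R[s2, tg] - r12 * R[tg, s1]) / d2, 0)
      sup <- tg[pd1 > base[s1, tg] + margin & pd2 > base[s2, tg] + margin]
      if (length(sup))
        hits[[length(hits) + 1L]] <- data.frame(
          seed1 = s1, seed2 = s2, target = sup, config = cfg,
          stringsAsFactors = FALSE)
    }
    rbindlist(hits)
  })
  all <- rbindlist(perConfig)
  if (nrow(all) == 0) return(emptyInteractions())
  pairTab <- all[, .(nConfigs = length(unique(config)),
                     targets = paste(sort(unique(target)), collapse = ",")),
                 by = .(seed1, seed2)]
  out <- as.data.frame(pairTab[nConfigs >= minConfigs])
  out[order(out$seed1, out$seed2), , drop = FALSE]
}

#' Display filter for seed networks
#'
#' Keeps only seeds that interact with at least one other seed and targets
#' with at least two seed edges (among the kept seeds), the filter applied
#' to the plotted networks.
#'
#' @param net a [SeedNetwork-class] object.
#' @return The filtered [SeedNetwork-class].
#' @export
displayFilter <- function(net) {
  stopifnot(is(net, "SeedNetwork"))
  it <- net@interactions
  keptSeeds <- intersect(net@seeds, unique(c(it$seed1, it$seed2)))
  ed <- net@edges[net@edges$seed %in% keptSeeds, , drop = FALSE]
  if (nrow(ed)) {
    tab <- table(ed$target)
    ed <- ed[ed$target %in% names(tab)[tab >= 2], , drop = FALSE]
  }
  SeedNetwork(keptSeeds, ed, it)
}

#' Classify cells as dox-exposed from transgene expression
#'
#' Splits the log transgene expression at the density minimum between its
#' two dominant modes; when the distribution is not bimodal the fallback
#' rule "any positive expression" is applied with a warning (degenerate
#' all-equal positive input labels every cell `TRUE`).
#'
#' @param counts gene-by-cell count matrix.
#' @param transgene transgene gene name (default `"iTransgene"`).
#' @return Named logical vector (`TRUE` = dox-exposed).
#' @export
classifyByTransgene <- function(counts, transgene = "iTransgene") {
  counts <- as.matrix(counts)
  if (!transgene %in% rownames(counts))
    stop("transgene ", transgene, " absent from the matrix")
  v <- log2(counts[transgene, ] + 1)
  if (all(v == 0)) return(setNames(rep(FALSE, length(v)), colnames(counts)))
  if (sd(v) == 0) {
    warning("transgene expression degenerate; using positive-expression rule")
    return(setNames(v > 0, colnames(counts)))
  }
  d <- density(v)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) >= 2) {
    top2 <- sort(locmax[order(-y[locmax])][1:2])
    valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
    thr <- d$x[valley]
  } else {
    warning("transgene distribution unimodal; using positive-expression rule")
    thr <- 0
  }
  setNames(v > thr, colnames(counts))
}

#' Recovery metrics against planted ground truth
#'
#' @param edges consensus edge table (from [consensusEdges()]) or a
#'   [SeedNetwork-class].
#' @param truthEdges `data.frame` with columns `seed`, `target`, `sign`
#'   (`"+"`/`"-"`), as in `simulationConfig()$edgeTable`.
#' @return List with `recall`, `precision`, `signAccuracy` (fraction of
#'   recovered directed edges carrying the planted sign), `nRecovered`,
#'   `nReported`, `dualSignTargets` (targets planted on two seeds with
#'   opposite signs) and `dualSignOpposite` (fraction of those recovered
#'   with opposite directions on the two seeds).
#' @export
recoveryMetrics <- function(edges, truthEdges) {
  if (is(edges, "SeedNetwork")) edges <- seedEdges(edges)
  key <- function(s, t) paste(s, t, sep = "\r")
  tk <- key(truthEdges$seed, truthEdges$target)
  ek <- key(edges$seed, edges$target)
  hit <- ek %in% tk
  recovered <- edges[hit, , drop = FALSE]
  truthSign <- setNames(ifelse(truthEdges$sign == "+", "positive",
                               "negative"), tk)
  directed <- recovered[recovered$direction != "other", , drop = FALSE]
  signAcc <- if (nrow(directed))
    mean(directed$direction ==
         truthSign[key(directed$seed, directed$target)]) else NA_real_

  # dual-sign motif: targets planted on two seeds with opposite signs
  tt <- as.data.table(truthEdges)[, .(n = .N,
                                      nsign = length(unique(sign))),
                                  by = target]
  dual <- tt[n >= 2 & nsign == 2]$target
  dualOk <- NA_real_
  if (length(dual)) {
    okFlags <- vapply(dual, function(tg) {
      tE <- truthEdges[truthEdges$target == tg, ]
      eE <- edges[edges$target == tg & edges$seed %in% tE$seed, ]
      if (nrow(eE) < nrow(tE)) return(FALSE)
      all(eE$direction == truthSign[key(eE$seed, eE$target)]) &&
        length(unique(eE$direction)) == 2
    }, logical(1))
    dualOk <- mean(okFlags)
  }
  list(recall = sum(hit) / length(tk),
       precision = if (nrow(edges)) sum(hit) / nrow(edges) else NA_real_,
       signAccuracy = signAcc,
       nRecovered = sum(hit), nReported = nrow(edges),
       dualSignTargets = dual, dualSignOpposite = dualOk)
}
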