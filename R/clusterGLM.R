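#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Quasi-Poisson rate tests for cluster composition
#'
#' For each cell-cluster category, fits a log-link quasi-Poisson GLM with
#' offset `log(plateTotal)` (modelling rates, not counts) on the cluster's
#' counts, with a factor distinguishing each +dox line from the pooled -dox
#' control group. Every (+dox line, cluster) combination yields one Wald
#' contrast against the control group -- 60 contrasts for 10 lines and 6
#' clusters -- and Benjamini-Hochberg adjustment is applied across all
#' contrasts jointly. The dispersion is estimated by Pearson chi-square over
#' residual degrees of freedom (the `stats::glm` quasi-Poisson default), so
#' point estimates coincide with Poisson maximum likelihood and only the
#' standard errors are scaled.
#'
#' @param tbl `data.frame` with columns `line`, `dox` (logical), `cluster`,
#'   `count`, `plateTotal` (see [simulateClusterCounts()]).
#' @param alpha significance level applied to adjusted p-values.
#' @return `data.frame` with one row per contrast: `line`, `cluster`,
#'   `rateRatio`, `se` (of the log rate ratio), `pvalue`, `padj`,
#'   `significant`.
#' @export
fitClusterGLM <- function(tbl, alpha = 0.05) {
  need <- c("line", "dox", "cluster", "count", "plateTotal")
  if (!all(need %in% names(tbl)))
    stop("count table must have columns ", paste(need, collapse = ", "))
  if (any(tbl$plateTotal <= 0)) stop("plate totals must be positive")
  if (any(tbl$count < 0)) stop("counts must be non-negative")
  tbl$dox <- as.logical(tbl$dox)

  res <- lapply(unique(tbl$cluster), function(cl) {
    sub <- tbl[tbl$cluster == cl, , drop = FALSE]
    if (!any(!sub$dox))
      stop("cluster ", cl, " has no -dox control samples")
    grp <- ifelse(sub$dox, as.character(sub$line), "control")
    sub$group <- factor(grp, levels = c("control", sort(unique(
      grp[grp != "control"]))))
    fit <- glm(count ~ group + offset(log(plateTotal)),
               family = quasipoisson(link = "log"), data = sub,
               control = list(epsilon = 1e-8, maxit = 100))
    sm <- summary(fit)$coefficients
    lev <- levels(sub$group)[-1]
    rows <- paste0("group", lev)
    data.frame(line = lev, cluster = cl,
               rateRatio = exp(sm[rows, "Estimate"]),
               se = sm[rows, "Std. Error"],
               pvalue = sm[rows, "Pr(>|t|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$padj <- bhAdjust(out$pvalue)
  out$significant <- out$padj < alpha
  out
}
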