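#' Seed-gene regulatory network
#'
#' Container for the result of seed-based network inference: directed
#' seed-to-target edges with a consensus direction label, and undirected
#' seed-seed interaction edges, each annotated with the target genes whose
#' association strengthened under conditioning.
#'
#' @slot seeds character vector of seed gene names.
#' @slot edges `data.frame` with columns `seed`, `target`, `direction`
#'   (one of `"positive"`, `"negative"`, `"other"`), `nConfigs` (number of
#'   configurations supporting the edge) and `meanDcor`.
#' @slot interactions `data.frame` with columns `seed1`, `seed2`,
#'   `nConfigs` and `targets` (comma-separated supporting target genes).
#'
#' @seealso [consensusEdges()], [inferSeedInteractions()], [displayFilter()]
#' @export
setClass("SeedNetwork",
  slots = c(seeds = "character", edges = "data.frame",
            interactions = "data.frame"))

setValidity("SeedNetwork", function(object) {
  msg <- NULL
  ed <- object@edges
  if (nrow(ed)) {
    need <- c("seed", "target", "direction", "nConfigs", "meanDcor")
    if (!all(need %in% names(ed)))
      msg <- c(msg, "edges must have columns seed, target, direction, nConfigs, meanDcor")
    else {
      if (!all(ed$direction %in% c("positive", "negative", "other")))
        msg <- c(msg, "edge directions must be positive/negative/other")
      if (!all(ed$seed %in% object@seeds))
        msg <- c(msg, "every edge seed must be a declared seed gene")
    }
  }
  it <- object@interactions
  if (nrow(it) && !all(c("seed1", "seed2") %in% names(it)))
    msg <- c(msg, "interactions must have columns seed1, seed2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SeedNetwork
#'
#' @param seeds character vector of seed gene names.
#' @param edges `data.frame` of consensus seed-to-target edges
#'   (see [consensusEdges()]).
#' @param interactions `data.frame` of seed-seed interactions
#'   (see [inferSeedInteractions()]); may be empty.
#' @return A [SeedNetwork-class] object.
#' @export
SeedNetwork <- function(seeds, edges, interactions = emptyInteractions()) {
  new("SeedNetwork", seeds = as.character(seeds),
      edges = as.data.frame(edges), interactions = as.data.frame(interactions))
}

emptyInteractions <- function() {
  data.frame(seed1 = character(), seed2 = character(),
             nConfigs = integer(), targets = character(),
             stringsAsFactors = FALSE)
}

#' Genome-wide signed correlation network
#'
#' Weighted signed gene-gene graph built from averaged Spearman correlations,
#' together with its per-gene centrality table.
#'
#' @slot graph an `igraph` object; edge attribute `weight` holds the signed
#'   average correlation.
#' @slot edges `data.frame` with columns `geneA`, `geneB`, `weight`.
#' @slot centrality `data.frame` with columns `gene`, `degree`,
#'   `betweenness`, `eigen` (filled by [networkCentralities()]).
#' @slot threshold numeric, the absolute-correlation threshold used.
#'
#' @seealso [buildSpearmanNetwork()], [networkCentralities()]
#' @export
setClass("GlobalNetwork",
  slots = c(graph = "ANY", edges = "data.frame", centrality = "data.frame",
            threshold = "numeric"))

setValidity("GlobalNetwork", function(object) {
  msg <- NULL
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(c("geneA", "geneB", "weight") %in% names(ed)))
      msg <- c(msg, "edges must have columns geneA, geneB, weight")
    else {
      if (any(ed$geneA == ed$geneB)) msg <- c(msg, "self-edges are not allowed")
      if (any(abs(ed$weight) <= object@threshold))
        msg <- c(msg, "every edge must satisfy |weight| > threshold")
    }
  }
  if (length(object@threshold) != 1L || object@threshold < 0)
    msg <- c(msg, "threshold must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})
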