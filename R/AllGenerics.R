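#' @rdname SeedNetwork-class
#' @param object,x a `SeedNetwork` or `GlobalNetwork` object.
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @rdname SeedNetwork-class
#' @export
setGeneric("seedEdges", function(x) standardGeneric("seedEdges"))

#' @rdname SeedNetwork-class
#' @export
setGeneric("seedInteractions", function(x) standardGeneric("seedInteractions"))

#' @rdname GlobalNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GlobalNetwork-class
#' @export
setGeneric("centralityTable", function(x) standardGeneric("centralityTable"))

#' @rdname GlobalNetwork-class
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname SeedNetwork-class
#' @export
setMethod("seedGenes", "SeedNetwork", function(x) x@seeds)

#' @rdname SeedNetwork-class
#' @export
setMethod("seedEdges", "SeedNetwork", function(x) x@edges)

#' @rdname SeedNetwork-class
#' @export
setMethod("seedInteractions", "SeedNetwork", function(x) x@interactions)

#' @rdname GlobalNetwork-class
#' @export
setMethod("networkEdges", "GlobalNetwork", function(x) x@edges)

#' @rdname GlobalNetwork-class
#' @export
setMethod("centralityTable", "GlobalNetwork", function(x) x@centrality)

#' @rdname GlobalNetwork-class
#' @export
setMethod("networkThreshold", "GlobalNetwork", function(x) x@threshold)

setMethod("show", "SeedNetwork", function(object) {
  ed <- object@edges
  cat("SeedNetwork with", length(object@seeds), "seed genes\n")
  cat(" ", nrow(ed), "seed->target edges")
  if (nrow(ed)) {
    tab <- table(factor(ed$direction,
                        levels = c("positive", "negative", "other")))
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
        sep = "")
  }
  cat("\n ", nrow(object@interactions), "seed-seed interactions\n")
})

setMethod("show", "GlobalNetwork", function(object) {
  ed <- object@edges
  cat("GlobalNetwork: ", length(unique(c(ed$geneA, ed$geneB))), " genes, ",
      nrow(ed), " edges (|avg rho| > ", object@threshold, ")\n", sep = "")
  if (nrow(ed))
    cat("  positive:", sum(ed$weight > 0), " negative:",
        sum(ed$weight < 0), "\n")
  if (nrow(object@centrality))
    cat("  centrality table:", nrow(object@centrality), "genes\n")
})
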