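#' Accessors for proxitome classes
#'
#' Small accessor generics: `bait()` and `baitCondition()` return the bait
#' symbol and condition of an [Interactome]; `preyNames()` its prey symbols
#' and `avgSpec()` the named AvgSpec vector; `normZ()`, `screenIds()` and
#' `geneIds()` expose a [ScreenProfile]; `cohortSize()` and `geneIds()` a
#' [SurvivalCohort]; `networkNodes()` / `networkEdges()` an
#' [InteractionNetwork]; `clusterIds()` and `leafOrder()` a
#' [ClusterAssignment].
#'
#' @param x the object.
#' @return the corresponding slot content (copies, never references).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bait", function(x) standardGeneric("bait"))
#' @rdname accessors
#' @export
setGeneric("baitCondition", function(x) standardGeneric("baitCondition"))
#' @rdname accessors
#' @export
setGeneric("preyNames", function(x) standardGeneric("preyNames"))
#' @rdname accessors
#' @export
setGeneric("avgSpec", function(x) standardGeneric("avgSpec"))
#' @rdname accessors
#' @export
setGeneric("normZ", function(x) standardGeneric("normZ"))
#' @rdname accessors
#' @export
setGeneric("screenIds", function(x) standardGeneric("screenIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @rdname accessors
setMethod("bait", "Interactome", function(x) x@bait)
#' @rdname accessors
setMethod("baitCondition", "Interactome", function(x) x@condition)
#' @rdname accessors
setMethod("preyNames", "Interactome", function(x) names(x@preys))
#' @rdname accessors
setMethod("avgSpec", "Interactome", function(x) x@preys)

#' @rdname accessors
setMethod("normZ", "ScreenProfile", function(x) x@normZ)
#' @rdname accessors
setMethod("screenIds", "ScreenProfile", function(x) colnames(x@normZ))
#' @rdname accessors
setMethod("geneIds", "ScreenProfile", function(x) rownames(x@normZ))

#' @rdname accessors
setMethod("cohortSize", "SurvivalCohort", function(x) length(x@time))
#' @rdname accessors
setMethod("geneIds", "SurvivalCohort", function(x) colnames(x@expression))

#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("clusterIds", "ClusterAssignment", function(x) x@clusters)
#' @rdname accessors
setMethod("leafOrder", "ClusterAssignment", function(x) x@leafOrder)

setMethod("show", "Interactome", function(object) {
    cat(sprintf("Interactome: bait %s [%s], %d preys\n", object@bait,
                object@condition, length(object@preys)))
    if (length(object@preys))
        cat("  preys: ",
            paste(head(names(object@preys), 6L), collapse = ", "),
            if (length(object@preys) > 6L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ScreenProfile", function(object) {
    cat(sprintf("ScreenProfile: %d genes x %d screens (%d missing cells)\n",
                nrow(object@normZ), ncol(object@normZ),
                sum(is.na(object@normZ))))
    if (ncol(object@normZ))
        cat("  screens: ", paste(head(colnames(object@normZ), 5L),
                                 collapse = ", "),
            if (ncol(object@normZ) > 5L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SurvivalCohort", function(object) {
    cat(sprintf(
        "SurvivalCohort [%s]: %d patients, %d genes, %d events (%.0f%%)\n",
        object@endpoint, length(object@time), ncol(object@expression),
        sum(object@event), 100 * mean(object@event)))
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("InteractionNetwork: %d nodes (%d baits), %d edges\n",
                nrow(object@nodes), sum(object@nodes$role == "bait"),
                nrow(object@edges)))
})

setMethod("show", "ClusterAssignment", function(object) {
    k <- if (length(object@clusters)) max(object@clusters) else 0L
    cat(sprintf("ClusterAssignment: %d genes in %d clusters (%s)\n",
                length(object@clusters), k, object@method))
})
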