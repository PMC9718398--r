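.canonEdges <- function(a, b, provenance) {
    keep <- a != b
    a <- a[keep]; b <- b[keep]; provenance <- provenance[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    data.frame(a = lo, b = hi, provenance = provenance,
               stringsAsFactors = FALSE)
}

.mergeProvenance <- function(edges) {
    key <- paste(edges$a, edges$b, sep = "\r")
    prov <- tapply(edges$provenance, key, function(p) {
        paste(sort(unique(unlist(strsplit(p, ";", fixed = TRUE)))),
              collapse = ";")
    })
    uniq <- edges[!duplicated(key), c("a", "b")]
    uniq$provenance <- as.character(prov[paste(uniq$a, uniq$b, sep = "\r")])
    uniq <- uniq[order(uniq$a, uniq$b), ]
    rownames(uniq) <- NULL
    uniq
}

#' Assemble a bait-prey proximity network
#'
#' Builds the star-shaped BioID network: one node per bait and per prey, one
#' undirected edge per (bait, prey) observation with provenance `"bioid"`.
#' Preys shared across baits connect to each of them. A prey symbol that is
#' itself a bait keeps the bait role.
#'
#' @param interactomes named list of [Interactome] objects.
#' @return an [InteractionNetwork].
#' @export
buildNetwork <- function(interactomes) {
    stopifnot(length(interactomes) >= 1L)
    baits <- vapply(interactomes, bait, character(1))
    preys <- unique(unlist(lapply(interactomes, preyNames)))
    nodes <- data.frame(
        symbol = c(baits, setdiff(preys, baits)),
        role = c(rep("bait", length(baits)),
                 rep("prey", length(setdiff(preys, baits)))),
        stringsAsFactors = FALSE)
    a <- rep(baits, vapply(interactomes, function(x) length(preyNames(x)),
                           integer(1)))
    b <- unlist(lapply(interactomes, preyNames), use.names = FALSE)
    edges <- .mergeProvenance(.canonEdges(a, b, rep("bioid", length(a))))
    new("InteractionNetwork", nodes = nodes, edges = edges)
}

#' Augment a proximity network with database prey-prey edges
#'
#' Adds interaction-catalogue edges (BioGRID-style exports, PSICQUIC dumps,
#' ...) between proteins already in the network; edges touching any symbol
#' outside the network are ignored, so the node set never changes. Duplicate
#' edges are merged and their provenance tags unioned; database edges carry
#' provenance `database:<source>`.
#'
#' @param network an [InteractionNetwork].
#' @param edgeTables named list `source -> data.frame(a, b)` (see
#'   [readEdgeTable()]).
#' @return the augmented [InteractionNetwork].
#' @export
augmentNetwork <- function(network, edgeTables) {
    stopifnot(is.list(edgeTables), !is.null(names(edgeTables)),
              all(nzchar(names(edgeTables))))
    nodes <- networkNodes(network)$symbol
    newEdges <- lapply(names(edgeTables), function(src) {
        tab <- edgeTables[[src]]
        a <- normalizeSymbols(tab$a); b <- normalizeSymbols(tab$b)
        keep <- a %in% nodes & b %in% nodes
        if (!any(keep)) return(NULL)
        .canonEdges(a[keep], b[keep],
                    rep(paste0("database:", src), sum(keep)))
    })
    all <- rbind(networkEdges(network), do.call(rbind, newEdges))
    new("InteractionNetwork", nodes = networkNodes(network),
        edges = .mergeProvenance(all))
}

#' Convert to igraph / export for external visualization
#'
#' `asIgraph()` returns an undirected [igraph::igraph] with node `role` and
#' edge `provenance` attributes; `writeNetwork()` writes GraphML and/or a
#' simple edge-list TSV importable by Cytoscape-class tools.
#'
#' @param network an [InteractionNetwork].
#' @return `asIgraph()`: an igraph object.
#' @export
asIgraph <- function(network) {
    igraph::graph_from_data_frame(networkEdges(network), directed = FALSE,
                                  vertices = networkNodes(network))
}

#' @rdname asIgraph
#' @param graphml,edgeList output paths (either may be `NULL`).
#' @export
writeNetwork <- function(network, graphml = NULL, edgeList = NULL) {
    if (!is.null(graphml))
        igraph::write_graph(asIgraph(network), graphml, format = "graphml")
    if (!is.null(edgeList))
        write.table(networkEdges(network), edgeList, sep = "\t",
                    quote = FALSE, row.names = FALSE)
    invisible(network)
}
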