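#' Gene-set collections in GMT format
#'
#' `readGMT()` parses the tab-separated GMT format (one set per line:
#' term id, description, then member genes); duplicate genes within a line
#' are counted once and symbols are normalised to the shared namespace.
#' `writeGMT()` is its inverse, used for fixtures and exports.
#'
#' @param path GMT file path.
#' @param source collection tag (GO-BP, KEGG, Reactome, CORUM, custom...).
#' @return `readGMT()`: a list with elements `sets` (named list of character
#'   vectors), `termNames` (named character) and `source`, class
#'   `"GeneSetCollection"`.
#' @export
readGMT <- function(path, source = "custom") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line(s) with fewer than 3 fields: line ",
             paste(short, collapse = ", "))
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicated term ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(fields, function(f) unique(normalizeSymbols(f[-(1:2)])))
    names(sets) <- ids
    if (any(lengths(sets) == 0L))
        stop("empty gene set(s): ",
             paste(ids[lengths(sets) == 0L], collapse = ", "))
    structure(list(sets = sets,
                   termNames = setNames(vapply(fields, `[[`, character(1), 2L),
                                        ids),
                   source = source),
              class = "GeneSetCollection")
}

#' @rdname readGMT
#' @param collection a `GeneSetCollection`.
#' @export
writeGMT <- function(collection, path) {
    lines <- vapply(names(collection$sets), function(id) {
        paste(c(id, collection$termNames[[id]], collection$sets[[id]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric overrepresentation analysis with FDR control
#'
#' Tests each gene set for overrepresentation in a query set drawn from a
#' finite universe. For a term with `K` universe genes, a query of size `n`
#' from a universe of size `N` and an observed overlap `k`, the p-value is
#' the upper-tail hypergeometric probability of an overlap of at least `k`;
#' q-values are Benjamini-Hochberg across all tested terms. Terms with no
#' gene in the universe are skipped; query genes outside the universe are
#' dropped with a warning. One-sided (enrichment only).
#'
#' @param query character vector of gene symbols.
#' @param collection a `GeneSetCollection` from [readGMT()].
#' @param universe character vector of background gene symbols; default is
#'   the union of all collection genes.
#' @param fdrMethod multiplicity correction passed to [stats::p.adjust()].
#' @return data.frame with columns `termId`, `termName`, `k`, `K`, `n`, `N`,
#'   `pValue`, `qValue`, sorted by p-value then term id.
#' @examples
#' gmt <- structure(list(sets = list(T1 = LETTERS[1:5]),
#'                       termNames = c(T1 = "demo"), source = "custom"),
#'                  class = "GeneSetCollection")
#' ora(LETTERS[1:5], gmt, universe = LETTERS[1:10])$pValue  # 1/choose(10,5)
#' @export
ora <- function(query, collection, universe = NULL, fdrMethod = "BH") {
    if (is.null(universe))
        universe <- unique(unlist(collection$sets, use.names = FALSE))
    universe <- unique(normalizeSymbols(universe))
    if (!length(universe)) stop("empty universe")
    query <- unique(normalizeSymbols(query))
    if (!length(query)) stop("empty query")
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning(length(outside),
                " query gene(s) outside the universe dropped")
        query <- intersect(query, universe)
        if (!length(query)) stop("no query genes left within the universe")
    }
    N <- length(universe); n <- length(query)
    rows <- lapply(names(collection$sets), function(id) {
        set <- intersect(collection$sets[[id]], universe)
        K <- length(set)
        if (K == 0L) return(NULL)
        k <- length(intersect(query, set))
        p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(termId = id,
                   termName = unname(collection$termNames[[id]]),
                   k = k, K = K, n = n, N = N, pValue = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        stop("no term overlaps the universe")
    out$qValue <- p.adjust(out$pValue, method = fdrMethod)
    out <- out[order(out$pValue, out$termId), ]
    rownames(out) <- NULL
    out
}

#' Dot-plot export of enrichment results
#'
#' Flattens an [ora()] table to the (term, -log10 p, overlap) triples used
#' for enrichment dot plots.
#'
#' @param result an [ora()] result.
#' @param alpha keep only terms with `pValue < alpha` (default 1 keeps all).
#' @return data.frame with columns `termId`, `termName`, `minusLog10P`, `k`.
#' @export
enrichmentDotPlot <- function(result, alpha = 1) {
    res <- result[result$pValue < alpha, , drop = FALSE]
    data.frame(termId = res$termId, termName = res$termName,
               minusLog10P = -log10(res$pValue), k = res$k,
               stringsAsFactors = FALSE)
}
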