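#' Multi-bait intersection specifications
#'
#' An intersection spec names the baits a prey must be seen by
#' (`include`, all of them) and the baits it must not be seen by (`exclude`,
#' none of them). The three complex-level interactomes of the classical
#' RAD51 paralogs are provided as ready-made specs: `bcdx2Spec()` (preys
#' exclusive to the four-membered RAD51B-RAD51C-RAD51D-XRCC2 complex, i.e.
#' absent from the XRCC3 BioID), `cx3Spec()` (preys exclusive to the
#' RAD51C-XRCC3 dimer) and `allCommonSpec()` (preys shared by all five
#' paralogs). Pass `exclusive = FALSE` to obtain the plain, non-exclusive
#' intersection instead.
#'
#' @param include character, baits the prey must appear in (non-empty).
#' @param exclude character, baits the prey must not appear in.
#' @return a list with elements `include` and `exclude`, class
#'   `"IntersectionSpec"`.
#' @examples
#' intersectionSpec(c("RAD51C", "XRCC3"), exclude = "RAD51B")
#' bcdx2Spec()
#' @export
intersectionSpec <- function(include, exclude = character()) {
    include <- unique(normalizeSymbols(include))
    exclude <- unique(normalizeSymbols(exclude))
    if (!length(include)) stop("'include' must be non-empty")
    if (length(intersect(include, exclude)))
        stop("'include' and 'exclude' must be disjoint")
    structure(list(include = include, exclude = exclude),
              class = "IntersectionSpec")
}

.PARALOGS <- c("RAD51B", "RAD51C", "RAD51D", "XRCC2", "XRCC3")

#' @rdname intersectionSpec
#' @param exclusive drop preys also seen by the complementary baits?
#' @export
bcdx2Spec <- function(exclusive = TRUE) {
    intersectionSpec(c("RAD51B", "RAD51C", "RAD51D", "XRCC2"),
                     if (exclusive) "XRCC3" else character())
}

#' @rdname intersectionSpec
#' @export
cx3Spec <- function(exclusive = TRUE) {
    intersectionSpec(c("RAD51C", "XRCC3"),
                     if (exclusive) c("RAD51B", "RAD51D", "XRCC2")
                     else character())
}

#' @rdname intersectionSpec
#' @export
allCommonSpec <- function() intersectionSpec(.PARALOGS)

.preySets <- function(interactomes) {
    stopifnot(is.list(interactomes), length(interactomes) >= 1L)
    if (is.null(names(interactomes)))
        names(interactomes) <- vapply(interactomes, bait, character(1))
    lapply(interactomes, preyNames)
}

#' Intersect bait interactomes under an inclusion/exclusion spec
#'
#' Computes the set of preys present in every `include` bait and absent from
#' every `exclude` bait: the complex-level interactome definition used to
#' derive, e.g., the BCDX2-exclusive, CX3-exclusive and all-common prey sets.
#'
#' @param interactomes named list of [Interactome] objects (names = baits).
#' @param spec an [intersectionSpec()].
#' @return sorted character vector of prey symbols.
#' @export
intersectPreys <- function(interactomes, spec) {
    sets <- .preySets(interactomes)
    unknown <- setdiff(c(spec$include, spec$exclude), names(sets))
    if (length(unknown))
        stop("unknown bait(s) in spec: ", paste(unknown, collapse = ", "),
             "; available: ", paste(names(sets), collapse = ", "))
    res <- Reduce(intersect, sets[spec$include])
    for (b in spec$exclude) res <- setdiff(res, sets[[b]])
    sort(res)
}

#' Upset decomposition of multi-bait prey sets
#'
#' Assigns every prey in the union of the interactomes to the signature of
#' exactly the baits that detected it, i.e. the disjoint cells of an upset
#' plot. Signatures are named by joining member baits with `"&"` in the
#' input bait order; cells partition the union.
#'
#' @param interactomes named list of [Interactome] objects.
#' @return named list, signature -> sorted prey character vector. Attribute
#'   `"cellSizes"` is a data.frame (signature, degree, size) sorted by
#'   decreasing size.
#' @export
upsetDecompose <- function(interactomes) {
    sets <- .preySets(interactomes)
    baits <- names(sets)
    allPreys <- sort(unique(unlist(sets, use.names = FALSE)))
    member <- vapply(sets, function(s) allPreys %in% s,
                     logical(length(allPreys)))
    if (length(allPreys) == 1L) member <- matrix(member, nrow = 1L)
    sig <- apply(member, 1L, function(m) paste(baits[m], collapse = "&"))
    cells <- split(allPreys, sig)
    cells <- lapply(cells, sort)
    sizes <- data.frame(
        signature = names(cells),
        degree = lengths(strsplit(names(cells), "&", fixed = TRUE)),
        size = lengths(cells), row.names = NULL)
    sizes <- sizes[order(-sizes$size, sizes$signature), ]
    rownames(sizes) <- NULL
    attr(cells, "cellSizes") <- sizes
    cells
}

#' Compare an interactome against a known-interaction catalogue
#'
#' Partitions the preys of an interactome into those with a curated
#' (bait, prey) edge in an interaction catalogue (BioGRID-style) and novel
#' ones, and reports the fold count `|preys| / max(1, |known|)`.
#'
#' @param interactome an [Interactome].
#' @param knownEdges data.frame with symbol columns `a`, `b` (undirected),
#'   e.g. from [readEdgeTable()].
#' @return list with `known`, `novel` (sorted character vectors) and
#'   `foldOverKnown`.
#' @export
noveltyReport <- function(interactome, knownEdges) {
    b <- bait(interactome)
    partner <- c(knownEdges$b[normalizeSymbols(knownEdges$a) == b],
                 knownEdges$a[normalizeSymbols(knownEdges$b) == b])
    partner <- unique(normalizeSymbols(partner))
    preys <- preyNames(interactome)
    known <- sort(intersect(preys, partner))
    list(known = known, novel = sort(setdiff(preys, known)),
         foldOverKnown = length(preys) / max(1L, length(known)))
}

#' Read an interaction edge table
#'
#' Accepts either a simple two-column TSV of symbol pairs or a BioGRID
#' TAB3-style export (columns "Official Symbol Interactor A"/"B"); column
#' names or indices can also be given explicitly.
#'
#' @param path TSV path.
#' @param columns length-2 vector of column names or indices holding the two
#'   interactor symbols; `NULL` autodetects (TAB3 headers, else columns 1-2).
#' @return data.frame with columns `a`, `b` (normalised symbols, self-pairs
#'   dropped, duplicates after canonical sorting removed).
#' @export
readEdgeTable <- function(path, columns = NULL) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", comment.char = "")
    if (is.null(columns)) {
        tab3 <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
        columns <- if (all(tab3 %in% names(df))) tab3 else c(1L, 2L)
    }
    a <- normalizeSymbols(df[[columns[[1]]]])
    b <- normalizeSymbols(df[[columns[[2]]]])
    keep <- nzchar(a) & nzchar(b) & a != b
    lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
    out <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}
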