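#' @import methods
#' @importFrom stats median phyper p.adjust qnorm pchisq rnbinom rexp rlnorm
#'   runif rpois sd cutree hclust dist cor as.dist setNames quantile rnorm
#'   complete.cases
#' @importFrom utils read.delim write.table head
NULL

.CONDITIONS <- c("untreated", "HU")

#' Interactome: one bait's filtered proximal prey set
#'
#' Holds the preys retained for a single bait in a single condition after
#' confidence and contaminant filtering, together with their average spectral
#' counts (AvgSpec). This is the unit object of all downstream set algebra,
#' abundance and network operations.
#'
#' @slot bait single gene symbol of the BirA*-tagged bait.
#' @slot condition `"untreated"` or `"HU"` (hydroxyurea replication stress).
#' @slot preys named numeric vector; names are prey gene symbols, values the
#'   AvgSpec evidence for each prey.
#'
#' @examples
#' it <- Interactome("RAD51C", "untreated", c(CHEK1 = 4.5, PLK1 = 2))
#' preyNames(it)
#' @export
setClass("Interactome",
    representation(bait = "character", condition = "character",
                   preys = "numeric"))

setValidity("Interactome", function(object) {
    msg <- character()
    if (length(object@bait) != 1L || is.na(object@bait) || !nzchar(object@bait))
        msg <- c(msg, "'bait' must be a single non-empty gene symbol")
    if (length(object@condition) != 1L || !object@condition %in% .CONDITIONS)
        msg <- c(msg, sprintf("'condition' must be one of: %s",
                              paste(.CONDITIONS, collapse = ", ")))
    p <- object@preys
    if (length(p)) {
        if (is.null(names(p)) || anyNA(names(p)) || any(!nzchar(names(p))))
            msg <- c(msg, "'preys' must be a named vector of gene symbols")
        else if (anyDuplicated(names(p)))
            msg <- c(msg, "duplicated prey symbols")
        if (any(!is.finite(p)) || any(p < 0))
            msg <- c(msg, "AvgSpec values must be finite and non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Interactome constructor.
#' @param bait,condition,preys see slots.
#' @export
Interactome <- function(bait, condition = "untreated", preys = numeric()) {
    new("Interactome", bait = as.character(bait),
        condition = as.character(condition), preys = preys)
}

#' ScreenProfile: gene-by-screen matrix of NormZ scores
#'
#' CRISPR chemogenomic profiles: each column is one screen (a drug / cell
#' line / source combination), each row a gene, each cell the gene-level NormZ
#' score from drugZ-style analysis. Negative NormZ means the knockout was
#' depleted (sensitization or essentiality). Missing cells (genes not covered
#' by a screen) are `NA`.
#'
#' @slot normZ numeric matrix, genes x screens; `NA` marks missing cells,
#'   all non-missing cells are finite.
#' @slot screenInfo data.frame of per-screen metadata (rows = screens, in
#'   column order of `normZ`); typically columns `drug`, `cellLine`, `source`.
#'
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("RAD51B", "RAD51C", "TP53"), c("s1", "s2")))
#' sp <- ScreenProfile(m)
#' screenIds(sp)
#' @export
setClass("ScreenProfile",
    representation(normZ = "matrix", screenInfo = "data.frame"))

setValidity("ScreenProfile", function(object) {
    msg <- character()
    m <- object@normZ
    if (!is.numeric(m)) msg <- c(msg, "'normZ' must be a numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "'normZ' needs gene rownames and screen colnames")
    else {
        if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicated gene rows")
        if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicated screen ids")
    }
    if (any(is.nan(m) | is.infinite(m)))
        msg <- c(msg, "normZ must be finite where not missing (NA)")
    if (nrow(object@screenInfo) &&
        !identical(rownames(object@screenInfo), colnames(m)))
        msg <- c(msg, "screenInfo rows must match normZ columns")
    if (length(msg)) msg else TRUE
})

#' @describeIn ScreenProfile constructor.
#' @param normZ,screenInfo see slots; `screenInfo` defaults to an empty frame.
#' @export
ScreenProfile <- function(normZ, screenInfo = NULL) {
    if (is.null(screenInfo))
        screenInfo <- data.frame(row.names = colnames(normZ))
    new("ScreenProfile", normZ = normZ, screenInfo = screenInfo)
}

#' SurvivalCohort: follow-up, events and per-gene expression
#'
#' A patient cohort for prognostic screening: right-censored follow-up time
#' (months), an event indicator (1 = death/relapse) and a patient x gene
#' expression matrix, tagged with the clinical endpoint.
#'
#' @slot time positive numeric, follow-up in months.
#' @slot event integer 0/1 event indicator, same length as `time`.
#' @slot expression numeric matrix, patients x genes; finite throughout.
#' @slot endpoint endpoint tag, `"OS"` (overall survival) or `"RFS"`
#'   (relapse-free survival).
#'
#' @examples
#' ex <- matrix(rlnorm(20), 10, 2, dimnames = list(NULL, c("SF3B2", "SNW1")))
#' sc <- SurvivalCohort(time = rexp(10, 0.02), event = rbinom(10, 1, 0.7),
#'                      expression = ex)
#' cohortSize(sc)
#' @export
setClass("SurvivalCohort",
    representation(time = "numeric", event = "integer",
                   expression = "matrix", endpoint = "character"))

setValidity("SurvivalCohort", function(object) {
    msg <- character()
    n <- length(object@time)
    if (anyNA(object@time) || any(object@time <= 0))
        msg <- c(msg, "follow-up times must be positive and non-missing")
    if (length(object@event) != n || anyNA(object@event) ||
        !all(object@event %in% c(0L, 1L)))
        msg <- c(msg, "'event' must be 0/1, non-missing, same length as time")
    if (nrow(object@expression) != n)
        msg <- c(msg, "expression must have one row per patient")
    if (any(!is.finite(object@expression)))
        msg <- c(msg, "expression must be finite")
    if (is.null(colnames(object@expression)))
        msg <- c(msg, "expression needs gene column names")
    if (!object@endpoint %in% c("OS", "RFS"))
        msg <- c(msg, "endpoint must be 'OS' or 'RFS'")
    if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalCohort constructor.
#' @param time,event,expression,endpoint see slots.
#' @export
SurvivalCohort <- function(time, event, expression, endpoint = "OS") {
    new("SurvivalCohort", time = as.numeric(time),
        event = as.integer(event), expression = expression,
        endpoint = endpoint)
}

#' InteractionNetwork: bait-prey graph with provenance-tagged edges
#'
#' A simple undirected graph over gene symbols. Nodes carry a role tag
#' (`bait` or `prey`); edges carry provenance (`bioid` for proximity edges,
#' `database:<source>` for augmentation edges). No self-loops, no duplicate
#' edges; edge endpoints are canonicalised (sorted within the pair).
#'
#' @slot nodes data.frame with columns `symbol`, `role`.
#' @slot edges data.frame with columns `a`, `b`, `provenance`
#'   (semicolon-joined sorted tags).
#'
#' @export
setClass("InteractionNetwork",
    representation(nodes = "data.frame", edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    nd <- object@nodes; ed <- object@edges
    if (!all(c("symbol", "role") %in% names(nd)))
        msg <- c(msg, "nodes need 'symbol' and 'role' columns")
    else {
        if (anyDuplicated(nd$symbol)) msg <- c(msg, "duplicated node symbols")
        if (!all(nd$role %in% c("bait", "prey")))
            msg <- c(msg, "node roles must be 'bait' or 'prey'")
    }
    if (!all(c("a", "b", "provenance") %in% names(ed)))
        msg <- c(msg, "edges need 'a', 'b', 'provenance' columns")
    else if (nrow(ed)) {
        if (!all(c(ed$a, ed$b) %in% nd$symbol))
            msg <- c(msg, "edge endpoints must be nodes")
        if (any(ed$a == ed$b)) msg <- c(msg, "self-loops are not allowed")
        if (any(ed$a > ed$b)) msg <- c(msg, "edge pairs must be sorted a < b")
        if (anyDuplicated(paste(ed$a, ed$b))) msg <- c(msg, "duplicate edges")
        if (any(!nzchar(ed$provenance)))
            msg <- c(msg, "edge provenance must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' ClusterAssignment: a cut hierarchical clustering of chemogenomic profiles
#'
#' @slot clusters named integer vector, gene -> cluster id in `1..k`; cluster
#'   ids are numbered by first appearance in input gene order.
#' @slot leafOrder character, genes in dendrogram leaf order.
#' @slot method single string describing distance/linkage used.
#'
#' @export
setClass("ClusterAssignment",
    representation(clusters = "integer", leafOrder = "character",
                   method = "character"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    cl <- object@clusters
    if (is.null(names(cl)) || anyNA(cl))
        msg <- c(msg, "clusters must be a named, non-missing integer vector")
    else if (length(cl) && !setequal(names(cl), object@leafOrder))
        msg <- c(msg, "leafOrder must be a permutation of clustered genes")
    if (length(msg)) msg else TRUE
})
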