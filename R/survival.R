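#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit estimate of the survivor function from
#' right-censored follow-up data: at each distinct event time `t_i` with
#' `d_i` events among `n_i` subjects at risk, the curve drops by the factor
#' `(1 - d_i / n_i)`. The estimate is right-continuous, non-increasing and
#' starts at `S(0) = 1`; with no censoring it equals one minus the empirical
#' CDF at event times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = event observed, 0 = censored).
#' @return data.frame with one row per distinct event time: `time`, `nRisk`,
#'   `nEvent`, `survival`.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(time, event) {
    if (!length(time)) stop("need at least one subject")
    if (anyNA(time) || any(time <= 0)) stop("times must be positive")
    event <- as.integer(event)
    stopifnot(length(event) == length(time), all(event %in% 0:1))
    etimes <- sort(unique(time[event == 1L]))
    if (!length(etimes))
        return(data.frame(time = numeric(), nRisk = integer(),
                          nEvent = integer(), survival = numeric()))
    nRisk <- vapply(etimes, function(t) sum(time >= t), integer(1))
    nEvent <- vapply(etimes, function(t) sum(time == t & event == 1L),
                     integer(1))
    data.frame(time = etimes, nRisk = nRisk, nEvent = nEvent,
               survival = cumprod(1 - nEvent / nRisk))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves: at each
#' distinct pooled event time the observed events in group A are compared to
#' their hypergeometric expectation given the pooled risk set, and the
#' squared summed deviation over the summed variance is referred to a 1-df
#' chi-square distribution. With no events (or no variance, e.g. one group
#' empty of risk at every event time) the statistic is 0 and p = 1.
#'
#' @param timeA,eventA follow-up and 0/1 event indicator, group A.
#' @param timeB,eventB same for group B.
#' @return list with `statistic` (chi-square, 1 df), `pValue`, and
#'   `observedA`/`expectedA` (for direction calls).
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
    if (!length(timeA) || !length(timeB)) stop("both groups must be non-empty")
    time <- c(timeA, timeB)
    event <- as.integer(c(eventA, eventB))
    grpA <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))
    etimes <- sort(unique(time[event == 1L]))
    O <- E <- V <- 0
    for (t in etimes) {
        atRisk <- time >= t
        n <- sum(atRisk); nA <- sum(atRisk & grpA)
        d <- sum(time == t & event == 1L)
        dA <- sum(time == t & event == 1L & grpA)
        O <- O + dA
        E <- E + d * nA / n
        if (n > 1L)
            V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
    }
    if (V <= 0)
        return(list(statistic = 0, pValue = 1, observedA = O, expectedA = E))
    stat <- (O - E)^2 / V
    list(statistic = stat, pValue = pchisq(stat, df = 1, lower.tail = FALSE),
         observedA = O, expectedA = E)
}

#' Prognostic screening of prey-gene expression
#'
#' For each gene, dichotomizes the cohort into low/high expression and tests
#' the two survival curves with the log-rank test — the screen used to ask
#' whether proximal interactors carry prognostic signal in patient cohorts.
#' `cutoffMode = "median"` splits at the per-gene median; `"best"` scans all
#' distinct expression values with quantile between 0.25 and 0.75 and keeps
#' the cutoff minimizing the log-rank p (anti-conservative by construction;
#' the number of scanned cutoffs is recorded for multiplicity disclosure).
#' No correction across genes is applied to the significance flag (raw
#' p < alpha), but a BH column is emitted for transparency.
#'
#' @param cohort a [SurvivalCohort].
#' @param genes genes to screen (default: all cohort genes).
#' @param cutoffMode `"median"` or `"best"`.
#' @param alpha raw significance level for the `significant` flag.
#' @return data.frame with one row per gene: `gene`, `cutoff`, `nLow`,
#'   `nHigh`, `statistic`, `pValue`, `qValue` (BH), `direction`
#'   (`"hazardous"` if the high-expression group has more events than
#'   expected, else `"protective"`), `significant`, `nCutoffsScanned`.
#' @export
screenGenes <- function(cohort, genes = NULL,
                        cutoffMode = c("median", "best"), alpha = 0.05) {
    cutoffMode <- match.arg(cutoffMode)
    stopifnot(alpha > 0, alpha <= 1)
    expr <- cohort@expression
    if (is.null(genes)) genes <- colnames(expr)
    miss <- setdiff(genes, colnames(expr))
    if (length(miss))
        stop("gene(s) not in cohort: ", paste(head(miss, 5L), collapse = ", "))
    time <- cohort@time; event <- cohort@event

    testCut <- function(x, cut) {
        high <- x > cut
        if (!any(high) || all(high)) return(NULL)
        res <- logrankTest(time[high], event[high], time[!high], event[!high])
        c(stat = res$statistic, p = res$pValue,
          excessHigh = res$observedA - res$expectedA,
          nLow = sum(!high), nHigh = sum(high))
    }

    rows <- lapply(genes, function(g) {
        x <- expr[, g]
        if (length(unique(x)) == 1L) {
            warning("constant expression for gene ", g)
            return(data.frame(gene = g, cutoff = x[1L],
                              nLow = length(x), nHigh = 0L, statistic = 0,
                              pValue = 1, direction = "none",
                              nCutoffsScanned = 0L,
                              stringsAsFactors = FALSE))
        }
        if (cutoffMode == "median") {
            cuts <- median(x)
        } else {
            q <- quantile(x, c(0.25, 0.75), type = 1)
            cuts <- sort(unique(x))
            cuts <- cuts[cuts >= q[1] & cuts <= q[2]]
            cuts <- cuts[vapply(cuts, function(ct) any(x > ct) && any(x <= ct),
                                logical(1))]
            if (!length(cuts)) cuts <- median(x)
        }
        best <- NULL; bestCut <- NA_real_
        for (ct in cuts) {
            r <- testCut(x, ct)
            if (is.null(r)) next
            if (is.null(best) || r["p"] < best["p"]) { best <- r; bestCut <- ct }
        }
        if (is.null(best)) {   # e.g. median equals the maximum
            ct <- min(x)
            best <- testCut(x, ct); bestCut <- ct
        }
        data.frame(gene = g, cutoff = bestCut,
                   nLow = as.integer(best["nLow"]),
                   nHigh = as.integer(best["nHigh"]),
                   statistic = unname(best["stat"]),
                   pValue = unname(best["p"]),
                   direction = if (best["excessHigh"] > 0) "hazardous"
                               else "protective",
                   nCutoffsScanned = length(cuts),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$qValue <- p.adjust(out$pValue, method = "BH")
    out$significant <- out$pValue < alpha
    out <- out[, c("gene", "cutoff", "nLow", "nHigh", "statistic", "pValue",
                   "qValue", "direction", "significant", "nCutoffsScanned")]
    rownames(out) <- NULL
    out
}

#' Per-gene KM curve table for a dichotomized gene
#'
#' Convenience export of the low/high survivor curves behind one row of
#' [screenGenes()].
#'
#' @param cohort a [SurvivalCohort].
#' @param gene gene symbol.
#' @param cutoff expression cutoff (patients with expression > cutoff form
#'   the high group); default median.
#' @return list of two KM tables, `low` and `high`.
#' @export
kmCurves <- function(cohort, gene, cutoff = NULL) {
    x <- cohort@expression[, gene]
    if (is.null(cutoff)) cutoff <- median(x)
    high <- x > cutoff
    list(low = kmEstimate(cohort@time[!high], cohort@event[!high]),
         high = kmEstimate(cohort@time[high], cohort@event[high]))
}
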