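#' Spectral abundance factor
#'
#' SAF corrects spectral-count evidence for protein size: the average
#' spectral count divided by the protein length in amino acids. Longer
#' proteins yield more peptides per molecule, so raw AvgSpec over-weights
#' them; SAF puts preys of different sizes on one abundance scale.
#'
#' @param avgSpec non-negative numeric, average spectral counts.
#' @param lengthAA positive integer protein lengths (amino acids); recycled.
#' @return numeric SAF values.
#' @examples
#' saf(10, 100)  # 0.1
#' @export
saf <- function(avgSpec, lengthAA) {
    if (any(!is.finite(lengthAA)) || any(lengthAA < 1))
        stop("protein length must be >= 1 aa")
    if (any(avgSpec < 0, na.rm = TRUE)) stop("avgSpec must be non-negative")
    avgSpec / lengthAA
}

#' log2-SAF abundance matrix across baits and conditions
#'
#' Builds the preys x (bait, condition) matrix of log2-transformed SAF
#' values used for abundance heatmaps. Preys unidentified by a bait are
#' imputed with an average spectral count of zero; with the default
#' `pseudo = 0` those cells are `-Inf` in the `log2SAF` assay and flagged in
#' the `imputed` assay, so they can be floored for display/clustering (see
#' [flooredLog2SAF()]) without pretending a count was observed.
#'
#' @param interactomes list of [Interactome] objects (any mix of baits and
#'   conditions; column names become `bait.condition`).
#' @param lengths named numeric vector, prey symbol -> protein length (aa);
#'   must cover every prey present in any interactome.
#' @param pseudo pseudocount added to AvgSpec before the SAF transform.
#' @param normalize `"saf"` (plain SAF) or `"nsaf"` (SAF divided by the
#'   per-column sum of SAF over observed preys).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays
#'   `log2SAF` (numeric) and `imputed` (logical) and colData columns `bait`,
#'   `condition`.
#' @export
buildAbundanceMatrix <- function(interactomes, lengths, pseudo = 0,
                                 normalize = c("saf", "nsaf")) {
    normalize <- match.arg(normalize)
    preys <- sort(unique(unlist(lapply(interactomes, preyNames))))
    miss <- setdiff(preys, names(lengths))
    if (length(miss))
        stop("no protein length for prey(s): ",
             paste(head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) ", ..." else "")
    cols <- vapply(interactomes,
                   function(it) paste(bait(it), baitCondition(it), sep = "."),
                   character(1))
    if (anyDuplicated(cols)) stop("duplicate (bait, condition) interactomes")
    spec <- matrix(0, nrow = length(preys), ncol = length(cols),
                   dimnames = list(preys, cols))
    imputed <- matrix(TRUE, nrow = length(preys), ncol = length(cols),
                      dimnames = list(preys, cols))
    for (j in seq_along(interactomes)) {
        v <- avgSpec(interactomes[[j]])
        spec[names(v), j] <- v
        imputed[names(v), j] <- FALSE
    }
    s <- saf(spec + pseudo, lengths[preys])
    if (normalize == "nsaf") {
        tot <- colSums(s * !imputed)
        tot[tot == 0] <- 1
        s <- sweep(s, 2L, tot, "/")
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2SAF = log2(s), imputed = imputed),
        colData = S4Vectors::DataFrame(
            bait = vapply(interactomes, bait, character(1)),
            condition = vapply(interactomes, baitCondition, character(1)),
            row.names = cols))
}

#' Floored log2-SAF matrix for display and clustering
#'
#' Replaces the `-Inf` sentinel of imputed (zero-count) cells by a finite
#' floor so that distance computations are well-defined and deterministic.
#'
#' @param se the SummarizedExperiment from [buildAbundanceMatrix()].
#' @param floor finite replacement value; default is the minimum observed
#'   (non-imputed, finite) log2-SAF minus 1.
#' @return numeric matrix.
#' @export
flooredLog2SAF <- function(se, floor = NULL) {
    m <- SummarizedExperiment::assay(se, "log2SAF")
    imp <- SummarizedExperiment::assay(se, "imputed")
    if (is.null(floor)) {
        obs <- m[!imp & is.finite(m)]
        floor <- if (length(obs)) min(obs) - 1 else 0
    }
    m[imp | !is.finite(m)] <- floor
    m
}

#' Differential BioID under replication stress
#'
#' For one bait assayed untreated and under hydroxyurea, computes the per-prey
#' log2 fold change of average spectral counts,
#' `log2((AvgSpec_HU + 1) / (AvgSpec_untreated + 1))`, over the union of both
#' prey sets; a prey absent from a condition contributes AvgSpec 0. The +1
#' offsets make the ratio defined at zero counts.
#'
#' @param untreated,hu [Interactome] objects for the same bait.
#' @return data.frame with columns `prey`, `bait`, `avgSpecUntreated`,
#'   `avgSpecHU`, `log2FC`, sorted by prey.
#' @examples
#' u <- Interactome("RAD51C", "untreated", c(A1 = 3))
#' h <- Interactome("RAD51C", "HU", c(A1 = 7))
#' differentialHU(u, h)$log2FC  # log2(8/4) = 1
#' @export
differentialHU <- function(untreated, hu) {
    if (bait(untreated) != bait(hu))
        stop("bait mismatch: '", bait(untreated), "' vs '", bait(hu), "'")
    preys <- sort(union(preyNames(untreated), preyNames(hu)))
    u <- setNames(rep(0, length(preys)), preys)
    h <- u
    u[preyNames(untreated)] <- avgSpec(untreated)
    h[preyNames(hu)] <- avgSpec(hu)
    data.frame(prey = preys, bait = bait(untreated),
               avgSpecUntreated = unname(u), avgSpecHU = unname(h),
               log2FC = unname(log2((h + 1) / (u + 1))),
               stringsAsFactors = FALSE)
}

#' Relative prey abundance over the bait's self-signal
#'
#' Dot-plot style normalisation: each prey's AvgSpec divided by the bait's
#' own AvgSpec in its BioID, capped at 1. Values near 1 indicate prey
#' recovered as abundantly as the bait itself (typical of stable complex
#' subunits).
#'
#' @param interactome an [Interactome].
#' @param baitSelfSpec the bait's own AvgSpec (> 0).
#' @return named numeric vector in \[0, 1\].
#' @export
relativePreyAbundance <- function(interactome, baitSelfSpec) {
    if (!is.finite(baitSelfSpec) || baitSelfSpec <= 0)
        stop("baitSelfSpec must be positive")
    pmin(avgSpec(interactome) / baitSelfSpec, 1)
}
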