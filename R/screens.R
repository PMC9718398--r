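#' Read a long-format gene-level NormZ table into a ScreenProfile
#'
#' Expects a TSV with columns `gene`, `screen`, `normZ` (one row per scored
#' gene per screen); genes absent from a screen are missing (`NA`) cells.
#'
#' @param path TSV path.
#' @param screenInfo optional per-screen metadata data.frame (rownames =
#'   screen ids).
#' @return a [ScreenProfile].
#' @export
readNormZTable <- function(path, screenInfo = NULL) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene", "screen", "normZ")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    df$gene <- normalizeSymbols(df$gene)
    genes <- unique(df$gene); screens <- unique(df$screen)
    m <- matrix(NA_real_, length(genes), length(screens),
                dimnames = list(genes, screens))
    m[cbind(match(df$gene, genes), match(df$screen, screens))] <-
        as.numeric(df$normZ)
    if (!is.null(screenInfo)) screenInfo <- screenInfo[screens, , drop = FALSE]
    ScreenProfile(m, screenInfo)
}

#' Read a guide-level CRISPR count table
#'
#' @param path TSV with columns `guide`, `gene`, `replicate`, `d0`, `d14`.
#' @return validated data.frame of guide counts.
#' @export
readGuideCounts <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("guide", "gene", "replicate", "d0", "d14")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    df$gene <- normalizeSymbols(df$gene)
    df$d0 <- as.numeric(df$d0); df$d14 <- as.numeric(df$d14)
    if (any(!is.finite(df$d0)) || any(!is.finite(df$d14)) ||
        any(df$d0 < 0) || any(df$d14 < 0))
        stop("guide counts must be finite and non-negative")
    g2gene <- tapply(df$gene, df$guide, function(g) length(unique(g)))
    if (any(g2gene > 1L))
        stop("guide(s) mapped to more than one gene: ",
             paste(head(names(g2gene)[g2gene > 1L], 5L), collapse = ", "))
    df
}

#' drugZ-style gene essentiality scoring from guide counts
#'
#' Scores gene knockouts as depleted (negative) or enriched (positive)
#' between the day-0 and day-14 populations of a dropout screen. Per
#' replicate, each sample's counts are depth-normalised to a common library
#' size, guide-level fold changes `log2((d14 + pseudo)/(d0 + pseudo))` are
#' z-scored against the empirical mean and SD of all guides in that
#' replicate, gene scores sum the guide z-scores across guides and
#' replicates divided by `sqrt(n)`, and gene scores are rank-based
#' inverse-normal transformed into NormZ. This is the simplified "drugZ-style"
#' scheme (the published algorithm adds empirical-Bayes variance moderation);
#' downstream classifiers only consume NormZ ranks and thresholds, and
#' externally computed NormZ tables can be supplied instead via
#' [readNormZTable()].
#'
#' @param guides guide-count data.frame as from [readGuideCounts()].
#' @param pseudo pseudocount added after depth normalisation (default 0.5).
#' @param libSize target library size for depth normalisation.
#' @return named numeric vector gene -> NormZ, sorted ascending (most
#'   depleted first).
#' @export
rankEssentiality <- function(guides, pseudo = 0.5, libSize = 1e7) {
    bad <- is.na(guides$gene) | !nzchar(guides$gene)
    if (any(bad)) {
        warning(sum(bad), " guide(s) without a gene assignment excluded")
        guides <- guides[!bad, , drop = FALSE]
    }
    if (!nrow(guides)) stop("no scorable guides")
    zs <- lapply(split(guides, guides$replicate), function(rep) {
        t0 <- sum(rep$d0); t14 <- sum(rep$d14)
        if (t0 <= 0 || t14 <= 0)
            stop("zero total counts in a sample of replicate '",
                 rep$replicate[1L], "'")
        n0 <- rep$d0 / t0 * libSize
        n14 <- rep$d14 / t14 * libSize
        fc <- log2((n14 + pseudo) / (n0 + pseudo))
        s <- sd(fc)
        if (!is.finite(s) || s == 0) s <- 1  # degenerate: no spread
        data.frame(gene = rep$gene, z = (fc - mean(fc)) / s)
    })
    zs <- do.call(rbind, zs)
    score <- tapply(zs$z, zs$gene, function(z) sum(z) / sqrt(length(z)))
    score <- score[!is.na(score)]
    m <- length(score)
    nz <- qnorm((rank(score, ties.method = "average") - 0.5) / m)
    sort(setNames(as.numeric(nz), names(score)))
}

.checkScreens <- function(profile, screens) {
    unknown <- setdiff(screens, screenIds(profile))
    if (length(unknown))
        stop("unknown screen id(s): ", paste(unknown, collapse = ", "))
}

#' Threshold classifiers on NormZ profiles
#'
#' `classifySensitizers()` returns the genes whose NormZ is strictly below
#' `threshold` in at least `minScreens` of the named screens — the rule used
#' to call olaparib sensitization (NormZ < -1 in >= 2 cell lines).
#' `classifyEssentials()` is the single-screen special case with the
#' essentiality cut (NormZ < -1.5 in the RPE1-hTERT dropout screen).
#' Missing cells never count toward the tally.
#'
#' @param profile a [ScreenProfile].
#' @param screens screen ids to tally over.
#' @param threshold strict NormZ cut (gene counts when `normZ < threshold`).
#' @param minScreens minimum number of qualifying screens.
#' @return sorted character vector of gene symbols.
#' @export
classifySensitizers <- function(profile, screens = screenIds(profile),
                                threshold = -1, minScreens = 1L) {
    .checkScreens(profile, screens)
    if (minScreens > length(screens))
        stop("minScreens (", minScreens, ") exceeds number of screens (",
             length(screens), ")")
    m <- normZ(profile)[, screens, drop = FALSE]
    hits <- rowSums(m < threshold, na.rm = TRUE) >= minScreens
    sort(rownames(m)[hits])
}

#' @rdname classifySensitizers
#' @param screen single screen id.
#' @export
classifyEssentials <- function(profile, screen, threshold = -1.5) {
    classifySensitizers(profile, screens = screen, threshold = threshold,
                        minScreens = 1L)
}

#' Replication-stress-modulated hits: differential BioID x HU screen
#'
#' Intersects the differential BioID signal with chemogenomic evidence: a
#' gene qualifies when its BioID abundance shifts under hydroxyurea
#' (`|log2FC| > fcCut` in at least one bait's differential table) and its
#' knockout scores in the chronic-HU CRISPR screen (`|NormZ| > zCut`).
#'
#' @param diff differential table(s) from [differentialHU()] (rbind several
#'   baits to screen across the complex).
#' @param profile a [ScreenProfile] containing the HU screen.
#' @param huScreen screen id of the chronic-HU screen.
#' @param fcCut absolute log2 fold-change cut (strict), default 1.
#' @param zCut absolute NormZ cut (strict), default 2.
#' @return sorted character vector of gene symbols.
#' @export
differentialHUHits <- function(diff, profile, huScreen, fcCut = 1,
                               zCut = 2) {
    .checkScreens(profile, huScreen)
    shifted <- unique(diff$prey[abs(diff$log2FC) > fcCut])
    m <- normZ(profile)
    z <- setNames(m[, huScreen], rownames(m))
    scoring <- names(z)[!is.na(z) & abs(z) > zCut]
    sort(intersect(shifted, scoring))
}

#' Hierarchical clustering of chemogenomic NormZ profiles
#'
#' Agglomerative clustering of genes by their NormZ response profile across
#' screens, cut into `k` clusters — the operation behind chemogenomic
#' sub-grouping of prey sets. Genes with no observed cell are dropped with a
#' warning; remaining missing cells are excluded pairwise from distances
#' (or imputed at 0 with `missing = "zero"`). Cluster ids are renumbered by
#' first appearance in input gene order, making the assignment deterministic
#' for fixed data and parameters.
#'
#' @param profile a [ScreenProfile].
#' @param k number of clusters (1 <= k <= number of genes).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson).
#' @param linkage `"complete"`, `"average"` or `"ward"` (Ward D2).
#' @param standardize z-score rows before computing distances?
#' @param missing `"pairwise"` exclusion or `"zero"` imputation.
#' @return a [ClusterAssignment].
#' @export
clusterProfiles <- function(profile, k,
                            distance = c("euclidean", "correlation"),
                            linkage = c("complete", "average", "ward"),
                            standardize = FALSE,
                            missing = c("pairwise", "zero")) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    missing <- match.arg(missing)
    m <- normZ(profile)
    allMiss <- rowSums(!is.na(m)) == 0L
    if (any(allMiss)) {
        warning(sum(allMiss), " gene(s) with no observed NormZ dropped")
        m <- m[!allMiss, , drop = FALSE]
    }
    if (k < 1L || k > nrow(m))
        stop("k must be between 1 and the number of clustered genes (",
             nrow(m), ")")
    if (missing == "zero") m[is.na(m)] <- 0
    if (standardize) {
        mu <- rowMeans(m, na.rm = TRUE)
        sdv <- apply(m, 1L, sd, na.rm = TRUE)
        sdv[!is.finite(sdv) | sdv == 0] <- 1
        m <- (m - mu) / sdv
    }
    d <- if (distance == "euclidean") dist(m)
         else as.dist(1 - cor(t(m), use = "pairwise.complete.obs"))
    if (any(is.na(d)))
        stop("undefined pairwise distances; consider missing = 'zero'")
    hc <- hclust(d, method = c(complete = "complete", average = "average",
                               ward = "ward.D2")[linkage])
    cl <- cutree(hc, k = k)
    # renumber clusters by first appearance in input order
    first <- cl[!duplicated(cl)]
    relabel <- setNames(seq_along(first), first)
    cl <- setNames(as.integer(relabel[as.character(cl)]), names(cl))
    new("ClusterAssignment", clusters = cl,
        leafOrder = hc$labels[hc$order],
        method = sprintf("%s distance, %s linkage, k = %d%s", distance,
                         linkage, as.integer(k),
                         if (standardize) ", standardized rows" else ""))
}
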