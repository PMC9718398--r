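# Small in-code fixtures and independent oracles shared across test files.

# a minimal well-formed prey table data.frame (not yet filtered)
makePreyRecords <- function() {
    data.frame(
        bait = c("RAD51C", "RAD51C", "XRCC3"),
        condition = "untreated",
        prey = c("CHEK1", "PLK1", "CHEK1"),
        avgSpec = c(4.5, 2, 3),
        uniquePeptides = c(3L, 1L, 2L),
        iProphetProb = c(0.99, 0.9, 0.95),
        lengthAA = c(476L, 603L, 476L),
        nReps = 2L, stringsAsFactors = FALSE)
}

writeTempPreyTable <- function(records, dialect = preyTableDialect()) {
    path <- tempfile(fileext = ".tsv")
    writePreyTable(records, path, dialect)
    path
}

# tiny interactome builder
it <- function(bait, preys, condition = "untreated") {
    Interactome(bait, condition,
                setNames(rep(1, length(preys)), preys))
}

# brute-force oracle: per-prey membership enumeration for include/exclude
bruteIntersect <- function(sets, include, exclude) {
    preys <- unique(unlist(sets))
    keep <- vapply(preys, function(p) {
        all(vapply(include, function(b) p %in% sets[[b]], logical(1))) &&
            !any(vapply(exclude, function(b) p %in% sets[[b]], logical(1)))
    }, logical(1))
    sort(preys[keep])
}

# brute-force oracle: exhaustive hypergeometric upper tail by enumerating
# every possible draw of n from N with K marked (N <= 12 keeps this fast)
enumHyperP <- function(k, K, n, N) {
    marked <- seq_len(K)
    draws <- utils::combn(N, n)
    overlaps <- colSums(matrix(draws %in% marked, nrow = n))
    mean(overlaps >= k)
}

# random 5-bait prey sets over a fixed universe
randomBaitSets <- function(baits = c("RAD51B", "RAD51C", "RAD51D",
                                     "XRCC2", "XRCC3"),
                           universeSize = 40, pMember = 0.4) {
    universe <- sprintf("P%03d", seq_len(universeSize))
    sets <- lapply(baits, function(b)
        universe[runif(universeSize) < pMember])
    names(sets) <- baits
    # guarantee non-empty interactomes
    for (b in baits)
        if (!length(sets[[b]])) sets[[b]] <- universe[1]
    sets
}

asInteractomes <- function(sets) {
    out <- lapply(names(sets), function(b) it(b, sets[[b]]))
    names(out) <- names(sets)
    out
}
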