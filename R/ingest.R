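#' Normalise gene symbols to a single namespace
#'
#' Upper-cases, strips surrounding whitespace and (optionally) drops an
#' isoform suffix after a delimiter. One shared namespace is what makes the
#' joins across BioID tables, screen tables, GMT collections and expression
#' cohorts well-defined.
#'
#' @param x character vector of symbols.
#' @param isoformDelim single character; everything from the first occurrence
#'   on is dropped. The default `"."` leaves ordinary HGNC symbols (including
#'   dash-containing ones such as NKX2-1) untouched.
#' @return normalised character vector.
#' @examples
#' normalizeSymbols(c(" chek1 ", "Sf3b2.1"))
#' @export
normalizeSymbols <- function(x, isoformDelim = ".") {
    x <- toupper(trimws(as.character(x)))
    if (nzchar(isoformDelim))
        x <- sub(paste0("\\", isoformDelim, ".*$"), "", x, fixed = FALSE)
    x
}

#' Default BioID contaminant list
#'
#' Classical BioID contaminants removed before any interactome analysis:
#' endogenously biotinylated carboxylases, lysozyme, keratins, ribosomal
#' subunits, and a set of recurrent promiscuous binders (AHNAK, PRKDC, TOP1,
#' HLCS, FLNB, PRKAA1, PRKAA2). Keratins and ribosomal subunits are matched
#' by symbol prefix (KRT*, RPL*, RPS*); everything else by exact symbol.
#'
#' @param extraSymbols,extraPrefixes additional exact symbols / prefixes.
#' @param file optional path to a text file (one symbol per line; lines ending
#'   in `*` are treated as prefixes) replacing the built-in defaults.
#' @return a list with elements `symbols` and `prefixes`, class
#'   `"ContaminantList"`.
#' @examples
#' cl <- defaultContaminants()
#' isContaminant(c("PRKDC", "KRT18", "CHEK1"), cl)
#' @export
defaultContaminants <- function(extraSymbols = character(),
                                extraPrefixes = character(),
                                file = NULL) {
    if (!is.null(file)) {
        ln <- trimws(readLines(file))
        ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
        pref <- sub("\\*$", "", ln[endsWith(ln, "*")])
        sym <- ln[!endsWith(ln, "*")]
    } else {
        sym <- c("AHNAK", "PRKDC", "TOP1", "HLCS", "FLNB", "PRKAA1", "PRKAA2",
                 "LYZ",
                 # endogenously biotinylated carboxylases
                 "ACACA", "ACACB", "PC", "PCCA", "PCCB", "MCCC1", "MCCC2")
        pref <- c("KRT", "RPL", "RPS")
    }
    out <- list(symbols = unique(normalizeSymbols(c(sym, extraSymbols))),
                prefixes = unique(normalizeSymbols(c(pref, extraPrefixes))))
    if (!length(out$symbols) && !length(out$prefixes))
        stop("contaminant list must be non-empty")
    class(out) <- "ContaminantList"
    out
}

#' @rdname defaultContaminants
#' @param symbols character vector of gene symbols to test.
#' @param contaminants a `ContaminantList`.
#' @export
isContaminant <- function(symbols, contaminants = defaultContaminants()) {
    symbols <- normalizeSymbols(symbols)
    hit <- symbols %in% contaminants$symbols
    for (p in contaminants$prefixes)
        hit <- hit | startsWith(symbols, p)
    hit
}

#' Column dialect for post-search prey tables
#'
#' Maps the fields of a prey record to the column headers of a tab-separated
#' post-search export. Override individual entries to read tables from other
#' search pipelines.
#'
#' @param ... named overrides, e.g. `PreyGene = "Gene"`.
#' @return named character vector of field -> header.
#' @export
preyTableDialect <- function(...) {
    d <- c(bait = "Bait", condition = "Condition", prey = "PreyGene",
           avgSpec = "AvgSpec", uniquePeptides = "UniquePeptides",
           iProphetProb = "iProphetProb", lengthAA = "LengthAA",
           nReps = "NReps")
    ov <- c(...)
    if (length(ov)) {
        bad <- setdiff(names(ov), names(d))
        if (length(bad))
            stop("unknown dialect fields: ", paste(bad, collapse = ", "))
        d[names(ov)] <- ov
    }
    d
}

.CONDITION_ALIASES <- c(untreated = "untreated", ctrl = "untreated",
                        control = "untreated", ns = "untreated",
                        hu = "HU", hydroxyurea = "HU")

#' Read a post-search BioID prey table
#'
#' Parses a tab-separated prey table into validated prey records (one row per
#' bait/condition/prey observation). Gene symbols are upper-cased and
#' whitespace-stripped; conditions are normalised to `untreated`/`HU`. Rows
#' violating the record invariants (iProphet probability outside \[0,1\],
#' negative or non-numeric AvgSpec, non-positive protein length, ...) are
#' dropped with a warning naming their line numbers; a missing required
#' column is a hard error.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect column mapping from [preyTableDialect()].
#' @param isoformDelim passed to [normalizeSymbols()].
#' @return data.frame with columns `bait`, `condition`, `prey`, `avgSpec`,
#'   `uniquePeptides`, `iProphetProb`, `lengthAA`, `nReps`; attribute
#'   `"rowErrors"` holds messages for any rejected rows.
#' @export
readPreyTable <- function(path, dialect = preyTableDialect(),
                          isoformDelim = ".") {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE)
    missing <- setdiff(unname(dialect), names(raw))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))

    df <- data.frame(
        bait = normalizeSymbols(raw[[dialect["bait"]]], isoformDelim),
        condition = tolower(trimws(raw[[dialect["condition"]]])),
        prey = normalizeSymbols(raw[[dialect["prey"]]], isoformDelim),
        avgSpec = suppressWarnings(as.numeric(raw[[dialect["avgSpec"]]])),
        uniquePeptides = suppressWarnings(
            as.integer(raw[[dialect["uniquePeptides"]]])),
        iProphetProb = suppressWarnings(
            as.numeric(raw[[dialect["iProphetProb"]]])),
        lengthAA = suppressWarnings(as.integer(raw[[dialect["lengthAA"]]])),
        nReps = suppressWarnings(as.integer(raw[[dialect["nReps"]]])),
        stringsAsFactors = FALSE)
    df$condition <- unname(.CONDITION_ALIASES[df$condition])

    # line number in file = data row + header line
    line <- seq_len(nrow(df)) + 1L
    probs <- character(nrow(df))
    fail <- rep(FALSE, nrow(df))
    note <- function(cond, what) {
        cond[is.na(cond)] <- TRUE
        probs[cond] <<- paste0(probs[cond], what, "; ")
        fail <<- fail | cond
    }
    note(is.na(df$avgSpec) | df$avgSpec < 0, "AvgSpec not a non-negative number")
    note(is.na(df$iProphetProb) | df$iProphetProb < 0 | df$iProphetProb > 1,
         "iProphet probability outside [0,1]")
    note(is.na(df$uniquePeptides) | df$uniquePeptides < 0,
         "unique-peptide count not a non-negative integer")
    note(is.na(df$lengthAA) | df$lengthAA < 1,
         "protein length < 1 aa")
    note(is.na(df$nReps) | df$nReps < 1, "replicate count < 1")
    note(is.na(df$condition), "unrecognised condition")
    note(!nzchar(df$prey) | !nzchar(df$bait), "empty gene symbol")

    rowErrors <- character()
    if (any(fail)) {
        rowErrors <- sprintf("line %d: %s", line[fail],
                             sub("; $", "", probs[fail]))
        warning(sum(fail), " malformed row(s) rejected:\n  ",
                paste(rowErrors, collapse = "\n  "), call. = FALSE)
        df <- df[!fail, , drop = FALSE]
    }
    key <- paste(df$bait, df$condition, df$prey)
    if (anyDuplicated(key))
        stop("duplicate (bait, condition, prey) rows: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    rownames(df) <- NULL
    attr(df, "rowErrors") <- rowErrors
    df
}

#' Write prey records back to the tab-separated table format
#'
#' Inverse of [readPreyTable()] under the same dialect; used for filtered
#' exports and for synthetic fixtures.
#'
#' @param records prey-record data.frame.
#' @param path output path.
#' @param dialect column mapping from [preyTableDialect()].
#' @export
writePreyTable <- function(records, path, dialect = preyTableDialect()) {
    out <- records[, names(dialect)]
    names(out) <- unname(dialect)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Confidence and contaminant filtering of prey records
#'
#' Applies the standard high-confidence rule for post-search BioID preys:
#' keep a record iff its iProphet probability is at least `minProb` (default
#' 0.9, inclusive), its unique-peptide count is at least `minUnique` (default
#' 1, inclusive, pooled across replicates) and its prey symbol is not on the
#' contaminant list. Record order is preserved. A per-rule removal report is
#' attached as attribute `"filterReport"`; records failing several rules are
#' counted under each rule they fail.
#'
#' @param records prey-record data.frame from [readPreyTable()].
#' @param minProb minimum iProphet probability in \[0,1\].
#' @param minUnique minimum unique peptides (>= 0).
#' @param contaminants a `ContaminantList`, or `NULL` to skip that rule.
#' @return the kept records, with attribute `"filterReport"` (a list with
#'   `input`, `kept`, `removedLowProb`, `removedFewUnique`,
#'   `removedContaminant`).
#' @export
filterPreys <- function(records, minProb = 0.9, minUnique = 1L,
                        contaminants = defaultContaminants()) {
    stopifnot(is.numeric(minProb), minProb >= 0, minProb <= 1,
              minUnique >= 0)
    lowProb <- records$iProphetProb < minProb
    fewUnique <- records$uniquePeptides < minUnique
    contam <- if (is.null(contaminants)) rep(FALSE, nrow(records))
              else isContaminant(records$prey, contaminants)
    keep <- !lowProb & !fewUnique & !contam
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "filterReport") <- list(
        input = nrow(records), kept = sum(keep),
        removedLowProb = sum(lowProb),
        removedFewUnique = sum(fewUnique),
        removedContaminant = sum(contam),
        minProb = minProb, minUnique = as.integer(minUnique))
    out
}

#' Build a bait's interactome from filtered prey records
#'
#' Collects the records of one (bait, condition) pair into an [Interactome].
#' Records are expected to be pre-filtered with [filterPreys()].
#'
#' @param records filtered prey-record data.frame.
#' @param bait bait gene symbol.
#' @param condition `"untreated"` or `"HU"`.
#' @return an [Interactome].
#' @export
buildInteractome <- function(records, bait, condition = "untreated") {
    bait <- normalizeSymbols(bait)
    avail <- unique(records$bait)
    if (!bait %in% avail)
        stop("bait '", bait, "' not in records; available baits: ",
             paste(sort(avail), collapse = ", "))
    sel <- records[records$bait == bait & records$condition == condition, ,
                   drop = FALSE]
    if (!nrow(sel))
        stop("no records for bait '", bait, "' in condition '", condition, "'")
    Interactome(bait, condition, setNames(sel$avgSpec, sel$prey))
}

#' Build all per-bait interactomes present in a record table
#'
#' @param records filtered prey-record data.frame.
#' @param condition condition to extract.
#' @return named list of [Interactome] objects (names = bait symbols, in
#'   order of first appearance).
#' @export
buildInteractomes <- function(records, condition = "untreated") {
    baits <- unique(records$bait[records$condition == condition])
    setNames(lapply(baits, buildInteractome, records = records,
                    condition = condition), baits)
}
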