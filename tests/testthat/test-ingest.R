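test_that("a well-formed table round-trips through write/read", {
    recs <- makePreyRecords()
    path <- writeTempPreyTable(recs)
    back <- readPreyTable(path)
    expect_equal(nrow(back), 3L)
    attr(back, "rowErrors") <- NULL
    expect_equal(back, recs)
})

test_that("malformed rows are rejected with their line numbers", {
    recs <- makePreyRecords()
    recs$iProphetProb[2] <- 1.2            # outside [0,1]
    path <- writeTempPreyTable(recs)
    expect_warning(back <- readPreyTable(path), "line 3")
    expect_equal(nrow(back), 2L)
    expect_match(attr(back, "rowErrors"), "iProphet")

    recs2 <- makePreyRecords()
    recs2$avgSpec <- as.character(recs2$avgSpec)
    recs2$avgSpec[1] <- "abc"
    path2 <- writeTempPreyTable(recs2)
    expect_warning(back2 <- readPreyTable(path2), "line 2")
    expect_equal(nrow(back2), 2L)
})

test_that("a missing required column is a hard error naming it", {
    recs <- makePreyRecords()
    path <- tempfile(fileext = ".tsv")
    out <- recs[, setdiff(names(recs), "iProphetProb")]
    names(out) <- preyTableDialect()[names(out)]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readPreyTable(path), "iProphetProb")
})

test_that("symbols are upper-cased, stripped, and conditions normalised", {
    recs <- makePreyRecords()
    recs$prey[1] <- " chek1 "
    recs$condition <- c("Untreated", "hu", "HU")
    path <- writeTempPreyTable(recs)
    back <- readPreyTable(path)
    expect_equal(back$prey[1], "CHEK1")
    expect_equal(back$condition, c("untreated", "HU", "HU"))
})

test_that("confidence filter is inclusive at both printed thresholds", {
    recs <- data.frame(bait = "B", condition = "untreated",
                       prey = c("BOUND", "LOWP", "NOPEP", "PRKDC"),
                       avgSpec = 1, uniquePeptides = c(1L, 3L, 0L, 5L),
                       iProphetProb = c(0.9, 0.8999, 0.99, 1),
                       lengthAA = 500L, nReps = 2L)
    kept <- filterPreys(recs)
    expect_equal(kept$prey, "BOUND")    # prob == 0.9 and 1 peptide pass
    rep <- attr(kept, "filterReport")
    expect_equal(rep$removedLowProb, 1L)
    expect_equal(rep$removedFewUnique, 1L)
    expect_equal(rep$removedContaminant, 1L)
    expect_equal(rep$kept + 3L, rep$input)
})

test_that("contaminant matching covers named genes and prefix classes", {
    cl <- defaultContaminants()
    expect_true(all(isContaminant(
        c("AHNAK", "PRKDC", "TOP1", "HLCS", "FLNB", "PRKAA1", "PRKAA2",
          "LYZ", "KRT18", "RPL11", "RPS6", "ACACA"), cl)))
    expect_false(any(isContaminant(c("CHEK1", "RAD51C", "TOP2A", "PCNA"), cl)))
    # overridable by file, prefixes marked with *
    f <- tempfile()
    writeLines(c("MYCONT", "ZZZ*"), f)
    cl2 <- defaultContaminants(file = f)
    expect_true(isContaminant("MYCONT", cl2))
    expect_true(isContaminant("ZZZ123", cl2))
    expect_false(isContaminant("PRKDC", cl2))
})

test_that("filtering is idempotent, monotone in minProb, and commutes", {
    set.seed(11)
    n <- 100
    recs <- data.frame(
        bait = "B", condition = "untreated",
        prey = sprintf("P%03d", seq_len(n)),
        avgSpec = runif(n, 0, 30),
        uniquePeptides = rpois(n, 1.2),
        iProphetProb = runif(n),
        lengthAA = sample(100:2000, n, replace = TRUE), nReps = 2L)
    recs$prey[sample(n, 10)] <- sample(c("PRKDC", "KRT8", "RPL3", "AHNAK"),
                                       10, replace = TRUE)
    recs <- recs[!duplicated(paste(recs$bait, recs$prey)), ]

    f1 <- filterPreys(recs)
    f2 <- filterPreys(f1)
    attr(f1, "filterReport") <- attr(f2, "filterReport") <- NULL
    expect_identical(f1, f2)                              # idempotent

    probs <- c(0.5, 0.7, 0.9, 0.95)
    kept <- lapply(probs, function(p) filterPreys(recs, minProb = p)$prey)
    for (i in seq_len(length(probs) - 1))
        expect_true(all(kept[[i + 1]] %in% kept[[i]]))    # monotone

    onlyConf <- filterPreys(recs, contaminants = NULL)
    confThenCont <- filterPreys(onlyConf, minProb = 0, minUnique = 0)
    contFirst <- recs[!isContaminant(recs$prey), ]
    contThenConf <- filterPreys(contFirst, contaminants = NULL)
    attr(confThenCont, "filterReport") <- NULL
    attr(contThenConf, "filterReport") <- NULL
    rownames(confThenCont) <- rownames(contThenConf) <- NULL
    expect_identical(confThenCont$prey, contThenConf$prey)  # commute
})

test_that("planted pass/fail labels are recovered on synthetic records", {
    cfg <- generatorConfig(seed = 42, nCommon = 40, nBcdx2 = 10, nCx3 = 5,
                           nBaitSpecific = 5, nBackground = 15,
                           nHuModulated = 5, decoyFrac = 0.2,
                           contaminantRate = 0.1)
    bio <- generateBioID(cfg)
    kept <- filterPreys(bio$records)
    planted <- names(bio$truth$category)
    # every kept prey is a planted prey: contaminants and decoys all removed
    expect_true(all(kept$prey %in% planted))
    expect_false(any(isContaminant(kept$prey)))
    expect_false(any(grepl("^DECOY", kept$prey)))
    # every planted detected row passes the filter
    plantedRows <- bio$records[bio$records$prey %in% planted, ]
    expect_equal(nrow(kept), nrow(plantedRows))
})

test_that("buildInteractome partitions records by bait and condition", {
    recs <- filterPreys(makePreyRecords())
    a <- buildInteractome(recs, "RAD51C")
    expect_setequal(preyNames(a), c("CHEK1", "PLK1"))
    expect_equal(unname(avgSpec(a)["CHEK1"]), 4.5)
    b <- buildInteractome(recs, "XRCC3")
    expect_setequal(preyNames(b), "CHEK1")
    expect_error(buildInteractome(recs, "RAD51B"), "RAD51C.*XRCC3")
    expect_error(buildInteractome(recs, "RAD51C", "HU"), "no records")
})

test_that("synthetic five-bait interactome sizes match planted membership", {
    cfg <- generatorConfig(seed = 7, nCommon = 30, nBcdx2 = 8, nCx3 = 4,
                           nBaitSpecific = 6, nBackground = 12,
                           nHuModulated = 3, noiseless = TRUE,
                           contaminantRate = 0)
    bio <- generateBioID(cfg)
    its <- buildInteractomes(filterPreys(bio$records))
    for (b in cfg$baits) {
        plantedSize <- sum(vapply(bio$truth$membership,
                                  function(m) b %in% m, logical(1)))
        expect_equal(length(preyNames(its[[b]])), plantedSize)
    }
})
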