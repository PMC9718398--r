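test_that("intersection handles identity and hand-checkable cases", {
    its <- list(A = it("A", c("X", "Y")), B = it("B", c("Y", "Z")),
                C = it("C", "Y"))
    expect_equal(intersectPreys(its, intersectionSpec("A")),
                 sort(c("X", "Y")))
    expect_equal(intersectPreys(its,
                                intersectionSpec(c("A", "B"), exclude = "C")),
                 character(0))
    expect_equal(intersectPreys(its, intersectionSpec(c("A", "B"))), "Y")
    expect_error(intersectPreys(its, intersectionSpec("NOPE")), "NOPE")
    expect_error(intersectionSpec("A", exclude = "A"), "disjoint")
    expect_error(intersectionSpec(character()), "non-empty")
})

test_that("intersection matches brute-force enumeration on random 5-bait sets", {
    set.seed(101)
    baits <- c("RAD51B", "RAD51C", "RAD51D", "XRCC2", "XRCC3")
    for (trial in 1:100) {
        sets <- randomBaitSets()
        its <- asInteractomes(sets)
        nInc <- sample(1:4, 1)
        include <- sample(baits, nInc)
        exclude <- sample(setdiff(baits, include),
                          sample(0:(5 - nInc), 1))
        spec <- intersectionSpec(include, exclude)
        expect_identical(intersectPreys(its, spec),
                         bruteIntersect(sets, include, exclude))
    }
})

test_that("include-set growth is anti-monotone", {
    set.seed(5)
    sets <- randomBaitSets()
    its <- asInteractomes(sets)
    small <- intersectPreys(its, intersectionSpec(c("RAD51B", "RAD51C")))
    large <- intersectPreys(its, intersectionSpec("RAD51B"))
    expect_true(all(small %in% large))
})

test_that("upset cells partition the union of prey sets", {
    # hand cases
    two <- list(A = it("A", "X"), B = it("B", "Y"))
    cells <- upsetDecompose(two)
    expect_setequal(names(cells), c("A", "B"))
    shared <- upsetDecompose(list(A = it("A", "X"), B = it("B", "X")))
    expect_equal(shared, list(`A&B` = "X"), ignore_attr = TRUE)

    set.seed(33)
    sets <- randomBaitSets(universeSize = 200, pMember = 0.3)
    its <- asInteractomes(sets)
    cells <- upsetDecompose(its)
    allPreys <- sort(unique(unlist(sets)))
    # disjoint cells covering the union, each prey in exactly one cell
    expect_equal(sort(unlist(cells, use.names = FALSE)), allPreys)
    expect_equal(sum(lengths(cells)), length(allPreys))
    # per-prey brute-force signature check
    for (p in sample(allPreys, 30)) {
        sig <- paste(names(sets)[vapply(sets, function(s) p %in% s,
                                        logical(1))], collapse = "&")
        expect_true(p %in% cells[[sig]])
    }
    sizes <- attr(cells, "cellSizes")
    expect_equal(sum(sizes$size), length(allPreys))
})

test_that("novelty report partitions preys against a catalogue", {
    a <- it("RAD51C", c("CHEK1", "PLK1", "POLA1"))
    empty <- data.frame(a = character(), b = character())
    r0 <- noveltyReport(a, empty)
    expect_equal(r0$novel, c("CHEK1", "PLK1", "POLA1"))
    expect_equal(r0$known, character(0))
    full <- data.frame(a = "RAD51C", b = c("CHEK1", "PLK1", "POLA1"))
    r1 <- noveltyReport(a, full)
    expect_equal(r1$novel, character(0))
    expect_equal(r1$foldOverKnown, 1)
    # symbol order in the edge table does not matter
    swapped <- data.frame(a = "CHEK1", b = "RAD51C")
    expect_equal(noveltyReport(a, swapped)$known, "CHEK1")
})

test_that("planted known-interaction overlap is recovered from fixtures", {
    cfg <- generatorConfig(seed = 9, nCommon = 40, nBcdx2 = 10, nCx3 = 5,
                           nBaitSpecific = 10, nBackground = 20,
                           nHuModulated = 5, noiseless = TRUE,
                           contaminantRate = 0)
    dir <- tempfile()
    fx <- writeFixtureDirectory(cfg, dir, knownFraction = 0.1)
    known <- readEdgeTable(fx$knownEdges)
    its <- buildInteractomes(filterPreys(fx$bioid$records))
    for (b in cfg$baits) {
        r <- noveltyReport(its[[b]], known)
        plantedKnown <- known$b[known$a == b | known$b == b]
        plantedKnown <- setdiff(c(plantedKnown,
                                  known$a[known$a == b | known$b == b]), b)
        expect_setequal(r$known, intersect(preyNames(its[[b]]), plantedKnown))
        expect_equal(length(r$known) + length(r$novel),
                     length(preyNames(its[[b]])))
    }
})

test_that("edge tables read plain two-column and BioGRID TAB3 headers", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("Official Symbol Interactor A\tOfficial Symbol Interactor B\tScore",
                 "chek1\tRAD51C\t0.9", "RAD51C\tCHEK1\t0.5", "X\tX\t1"), f)
    ed <- readEdgeTable(f)
    expect_equal(nrow(ed), 1L)   # canonicalised duplicate + self pair dropped
    expect_equal(ed$a, "CHEK1")
    expect_equal(ed$b, "RAD51C")
})
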