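makeProfile <- function(m) ScreenProfile(m)

test_that("threshold classifiers match hand checks and boundaries", {
    m <- rbind(HIT = c(-1.2, -0.5, -3.0),
               EDGE = c(-1.0, -1.0, -1.0),
               NEG = c(0.5, 1.2, -0.2))
    colnames(m) <- c("s1", "s2", "s3")
    p <- makeProfile(m)
    expect_equal(classifySensitizers(p, minScreens = 2), "HIT")
    expect_equal(classifySensitizers(p, minScreens = 1), "HIT")
    # strict inequality at the boundary
    expect_false("EDGE" %in% classifySensitizers(p, minScreens = 1))
    expect_error(classifySensitizers(p, c("s1", "s2"), minScreens = 3),
                 "exceeds")
    expect_error(classifySensitizers(p, "nope"), "unknown screen")
    # essentiality: strict at -1.5; positive NormZ never qualifies
    m2 <- cbind(ess = c(TP53 = 2.5, RAD51C = -3, EDGE = -1.5))
    expect_equal(classifyEssentials(makeProfile(m2), "ess"), "RAD51C")
})

test_that("classifiers agree with brute-force counting and are monotone", {
    set.seed(21)
    for (trial in 1:20) {
        m <- matrix(rnorm(50 * 4), 50, 4,
                    dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:4)))
        m[sample(length(m), 30)] <- NA
        p <- makeProfile(m)
        thr <- runif(1, -2, 0); ms <- sample(1:4, 1)
        brute <- sort(rownames(m)[vapply(seq_len(nrow(m)), function(i)
            sum(m[i, ] < thr, na.rm = TRUE) >= ms, logical(1))])
        expect_identical(classifySensitizers(p, threshold = thr,
                                             minScreens = ms), brute)
        # relaxing the threshold never removes genes
        relaxed <- classifySensitizers(p, threshold = thr + 0.5,
                                       minScreens = ms)
        expect_true(all(classifySensitizers(p, threshold = thr,
                                            minScreens = ms) %in% relaxed))
    }
})

test_that("drugZ-style scoring is centred under the null and depth-invariant", {
    cfg <- generatorConfig(seed = 13, screenGenes = 300, nEssentials = 0,
                           essentialEffect = 1)
    scr <- generateScreen(cfg)
    nz <- rankEssentiality(scr$guides)
    expect_equal(length(nz), 300L)
    expect_true(all(is.finite(nz)))
    expect_lt(abs(mean(nz)), 0.05)   # inverse-normal transform is centred
    # identical D0/D14 counts: finite and centred near zero
    g0 <- scr$guides; g0$d14 <- g0$d0
    nz0 <- rankEssentiality(g0)
    expect_true(all(is.finite(nz0)))
    expect_lt(abs(mean(nz0)), 0.05)
    # multiplying all counts in one sample by a constant changes nothing
    g2 <- scr$guides
    g2$d14[g2$replicate == "R1"] <- g2$d14[g2$replicate == "R1"] * 7
    expect_equal(rankEssentiality(g2), nz, tolerance = 1e-9)
    # zero total counts in a sample is a hard error
    g3 <- scr$guides; g3$d0[g3$replicate == "R1"] <- 0
    expect_error(rankEssentiality(g3), "zero total")
})

test_that("planted essentials are recovered and permutation destroys signal", {
    cfg <- generatorConfig(seed = 4)   # 2000 genes, 50 essentials at 10%
    scr <- generateScreen(cfg)
    nz <- rankEssentiality(scr$guides)
    k <- length(scr$truth$essentials)
    bottom <- names(sort(nz))[seq_len(k)]
    recall <- mean(scr$truth$essentials %in% bottom)
    expect_gte(recall, 0.9)
    expect_true(all(nz[scr$truth$essentials] < 0))
    # permuting the guide -> gene map reduces recall to about chance
    set.seed(99)
    perm <- scr$guides
    map <- unique(perm[, c("guide", "gene")])
    map$gene <- sample(map$gene)
    perm$gene <- map$gene[match(perm$guide, map$guide)]
    nzP <- rankEssentiality(perm)
    bottomP <- names(sort(nzP))[seq_len(k)]
    expect_lt(mean(scr$truth$essentials %in% bottomP), 0.2)
})

test_that("differential HU hits require both the fold change and the screen", {
    d <- data.frame(prey = c("UPSHIFT", "FLAT", "SHIFTNOSCREEN"),
                    bait = "RAD51C",
                    avgSpecUntreated = c(3, 5, 2), avgSpecHU = c(15, 5, 9),
                    log2FC = c(2, 0, 1.7))
    m <- cbind(HU = c(UPSHIFT = -2.5, FLAT = -3, SHIFTNOSCREEN = -1.0))
    p <- makeProfile(m)
    expect_equal(differentialHUHits(d, p, "HU"), "UPSHIFT")
    # boundary is strict on both cuts
    m2 <- cbind(HU = c(UPSHIFT = 2.0))
    expect_equal(differentialHUHits(d, makeProfile(m2), "HU"), character(0))
})

test_that("profile clustering recovers planted blobs deterministically", {
    set.seed(8)
    blob1 <- matrix(rnorm(20 * 5, mean = -3, sd = 0.3), 20, 5)
    blob2 <- matrix(rnorm(20 * 5, mean = 3, sd = 0.3), 20, 5)
    m <- rbind(blob1, blob2)
    dimnames(m) <- list(sprintf("G%02d", 1:40), paste0("s", 1:5))
    p <- makeProfile(m)
    cl <- clusterProfiles(p, k = 2)
    expect_equal(unname(clusterIds(cl)[1:20]), rep(1L, 20))
    expect_equal(unname(clusterIds(cl)[21:40]), rep(2L, 20))
    # k = 1 puts everything together
    expect_true(all(clusterIds(clusterProfiles(p, k = 1)) == 1L))
    # duplicating every gene leaves per-original memberships unchanged
    m2 <- rbind(m, `rownames<-`(m, paste0(rownames(m), "_dup")))
    cl2 <- clusterProfiles(makeProfile(m2), k = 2)
    expect_equal(unname(clusterIds(cl2)[rownames(m)]),
                 unname(clusterIds(cl)[rownames(m)]))
    expect_error(clusterProfiles(p, k = 41), "between 1 and")
    # all-missing genes are dropped with a warning
    m3 <- rbind(m, GXX = NA_real_)
    expect_warning(cl3 <- clusterProfiles(makeProfile(m3), k = 2), "dropped")
    expect_false("GXX" %in% names(clusterIds(cl3)))
})

test_that("NormZ tables round-trip through the long TSV reader", {
    m <- matrix(c(-1.5, 0.3, NA, 2.2), 2, 2,
                dimnames = list(c("G1", "G2"), c("sA", "sB")))
    long <- data.frame(gene = c("G1", "G2", "G2"),
                       screen = c("sA", "sA", "sB"),
                       normZ = c(-1.5, 0.3, 2.2))
    f <- tempfile(fileext = ".tsv")
    write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
    p <- readNormZTable(f)
    expect_equal(normZ(p), m)
})
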