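test_that("product-limit estimate matches hand arithmetic", {
    # no censoring: S = 2/3, 1/3, 0 at t = 1, 2, 3
    km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km$survival, c(2/3, 1/3, 0))
    # all censored: S stays at 1 (no event rows)
    expect_equal(nrow(kmEstimate(c(1, 2, 3), c(0, 0, 0))), 0L)
    # mixed hand-computed table: events at 1 (n=5) and 3 (n=3), censor at 2
    km2 <- kmEstimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 0))
    expect_equal(km2$time, c(1, 3))
    expect_equal(km2$nRisk, c(5L, 3L))
    expect_equal(km2$survival, c(4/5, 4/5 * 2/3))
    expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("product-limit agrees with the survival package on random data", {
    skip_if_not_installed("survival")
    set.seed(14)
    for (i in 1:10) {
        n <- sample(10:60, 1)
        time <- round(rexp(n, 0.1), 2) + 0.01
        event <- rbinom(n, 1, 0.7)
        if (!any(event == 1)) event[1] <- 1L
        km <- kmEstimate(time, event)
        sf <- survival::survfit(survival::Surv(time, event) ~ 1)
        ref <- summary(sf, times = km$time)
        expect_equal(km$survival, ref$surv, tolerance = 1e-12)
    }
})

test_that("no-censoring KM equals one minus the empirical CDF", {
    set.seed(6)
    time <- rexp(40, 0.2) + 0.01
    km <- kmEstimate(time, rep(1, 40))
    expect_equal(km$survival, 1 - ecdf(time)(km$time), tolerance = 1e-12)
})

test_that("log-rank is symmetric, null at identity, matches survdiff", {
    tA <- c(1, 2, 4, 7); eA <- c(1, 0, 1, 1)
    same <- logrankTest(tA, eA, tA, eA)
    expect_equal(same$statistic, 0)
    expect_equal(same$pValue, 1)
    tB <- c(2, 3, 5, 9); eB <- c(1, 1, 0, 1)
    ab <- logrankTest(tA, eA, tB, eB)
    ba <- logrankTest(tB, eB, tA, eA)
    expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
    # zero events in both groups
    z <- logrankTest(c(1, 2), c(0, 0), c(3), c(0))
    expect_equal(z$statistic, 0); expect_equal(z$pValue, 1)

    skip_if_not_installed("survival")
    set.seed(31)
    for (i in 1:10) {
        nA <- sample(8:30, 1); nB <- sample(8:30, 1)
        tA <- rexp(nA, 0.1) + 0.01; tB <- rexp(nB, 0.2) + 0.01
        eA <- rbinom(nA, 1, 0.8); eB <- rbinom(nB, 1, 0.8)
        if (!any(c(eA, eB) == 1)) eA[1] <- 1L
        mine <- logrankTest(tA, eA, tB, eB)
        sd <- survival::survdiff(
            survival::Surv(c(tA, tB), c(eA, eB)) ~
                rep(1:2, c(nA, nB)))
        expect_equal(mine$statistic, unname(sd$chisq), tolerance = 1e-8)
    }
})

test_that("chi-square log-rank p sits inside the permutation interval", {
    set.seed(55)
    tA <- rexp(12, 0.05) + 0.01; tB <- rexp(12, 0.25) + 0.01
    eA <- rep(1L, 12); eB <- rep(1L, 12)
    obs <- logrankTest(tA, eA, tB, eB)
    time <- c(tA, tB); event <- c(eA, eB)
    B <- 2000
    stats <- replicate(B, {
        idx <- sample(24, 12)
        logrankTest(time[idx], event[idx], time[-idx],
                    event[-idx])$statistic
    })
    permP <- mean(stats >= obs$statistic)
    ci <- permP + c(-1, 1) * 3 * sqrt(permP * (1 - permP) / B + 1e-6)
    expect_gte(obs$pValue, max(0, ci[1]))
    expect_lte(obs$pValue, min(1, ci[2] + 0.01))
})

test_that("gene screen flags planted hazards and respects alpha", {
    cfg <- generatorConfig(seed = 17, cohortGenes = 30, nHazardous = 3)
    coh <- generateCohort(cfg)
    res <- screenGenes(coh$cohort, cutoffMode = "median")
    expect_true(all(res$pValue[match(coh$truth$hazardous, res$gene)] < 0.05))
    expect_true(all(res$direction[match(coh$truth$hazardous,
                                        res$gene)] == "hazardous"))
    expect_equal(res$nLow + res$nHigh, rep(cohortSize(coh$cohort), 30))
    # alpha = 1 flags everything
    resAll <- screenGenes(coh$cohort, cutoffMode = "median", alpha = 1)
    expect_true(all(resAll$significant))
    # constant expression yields p = 1 with a warning
    expr <- coh$cohort@expression
    expr[, 1] <- 5
    flat <- SurvivalCohort(coh$cohort@time, coh$cohort@event, expr)
    expect_warning(rf <- screenGenes(flat, genes = colnames(expr)[1]),
                   "constant")
    expect_equal(rf$pValue, 1)
    expect_error(screenGenes(coh$cohort, genes = "NOSUCH"), "NOSUCH")
})

test_that("best-cutoff p is never above the median-cutoff p", {
    cfg <- generatorConfig(seed = 23, cohortSize = 120, cohortGenes = 15,
                           nHazardous = 2)
    coh <- generateCohort(cfg)
    med <- screenGenes(coh$cohort, cutoffMode = "median")
    best <- screenGenes(coh$cohort, cutoffMode = "best")
    expect_true(all(best$pValue <= med$pValue + 1e-12))
    expect_true(all(best$nCutoffsScanned >= 1))
    # the scanned cutoff count is disclosed and exceeds one for real scans
    expect_gt(median(best$nCutoffsScanned), 1)
})

test_that("per-gene KM curve export splits at the cutoff", {
    cfg <- generatorConfig(seed = 29, cohortSize = 80, cohortGenes = 4,
                           nHazardous = 1)
    coh <- generateCohort(cfg)
    g <- geneIds(coh$cohort)[1]
    cv <- kmCurves(coh$cohort, g)
    expect_true(all(diff(cv$low$survival) <= 0))
    expect_true(all(diff(cv$high$survival) <= 0))
    expect_true(all(cv$low$survival >= 0 & cv$low$survival <= 1))
})
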