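#' Configuration for the synthetic-data generator
#'
#' One validated configuration object drives every synthetic input the
#' pipeline consumes. Defaults emulate the study design around the five
#' classical RAD51 paralog baits: two biological replicates per bait per
#' condition (untreated / hydroxyurea), planted complex structure at the
#' published interactome sizes (945 all-common, 97 BCDX2-exclusive, 46
#' CX3-exclusive preys), classical BioID contaminants, negative-binomial
#' spectral counts, a TKO-style multi-guide dropout screen and an
#' expression-linked survival cohort. `noiseless = TRUE` switches off
#' detection dropout, decoys, replicate noise and missing screen cells so
#' that set-level recoveries are exact by construction.
#'
#' @param seed integer RNG seed (mandatory; all generators derive their
#'   streams from it).
#' @param baits bait gene symbols.
#' @param nCommon,nBcdx2,nCx3 planted sizes of the all-common,
#'   BCDX2-exclusive and CX3-exclusive prey sets.
#' @param nBaitSpecific preys private to each single bait.
#' @param nBackground preys with random 1-3 bait membership signatures
#'   (never a planted complex signature).
#' @param countMean,countDispersion negative-binomial mean / size for
#'   spectral counts; per-prey means are log-normal around `countMean`.
#' @param detectionProb probability a member prey is detected in a bait's
#'   table (1 in noiseless mode).
#' @param decoyFrac fraction of low-confidence decoy rows added per table.
#' @param contaminantRate fraction of contaminant rows added per table.
#' @param nReplicates biological replicates averaged into AvgSpec.
#' @param nHuModulated number of HU-responsive preys (drawn from the
#'   all-common set); their spectral mean is shifted by `huLog2Effect` under
#'   HU.
#' @param huLog2Effect log2 shift of HU-responsive prey abundance.
#' @param screenGenes,guidesPerGene,screenReplicates dropout-screen geometry.
#' @param nEssentials planted essential genes in the dropout screen.
#' @param essentialEffect day-14 fitness of essentials (0.1 = depleted to
#'   10% of the day-0 expectation; 1 = no effect).
#' @param screenCountMean,screenCountDispersion NB parameters for guide
#'   counts.
#' @param cohortSize,cohortGenes survival-cohort geometry.
#' @param nHazardous planted prognostic genes; `hazardRatio` multiplies the
#'   baseline hazard when their expression is above the cohort median.
#' @param hazardRatio,baselineHazard,censorHazard,followUpMax survival model
#'   (hazards per month; follow-up administratively censored at
#'   `followUpMax`).
#' @param noiseless exact mode for set-level recovery tests.
#' @return validated list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(seed,
                            baits = c("RAD51B", "RAD51C", "RAD51D",
                                      "XRCC2", "XRCC3"),
                            nCommon = 945L, nBcdx2 = 97L, nCx3 = 46L,
                            nBaitSpecific = 60L, nBackground = 300L,
                            countMean = 10, countDispersion = 2,
                            detectionProb = 0.95, decoyFrac = 0.05,
                            contaminantRate = 0.03, nReplicates = 2L,
                            nHuModulated = 80L, huLog2Effect = 2,
                            screenGenes = 2000L, guidesPerGene = 4L,
                            screenReplicates = 2L, nEssentials = 50L,
                            essentialEffect = 0.1,
                            screenCountMean = 500, screenCountDispersion = 10,
                            cohortSize = 500L, cohortGenes = 200L,
                            nHazardous = 5L, hazardRatio = 2,
                            baselineHazard = 0.02, censorHazard = 0.01,
                            followUpMax = 120,
                            noiseless = FALSE) {
    if (missing(seed) || is.na(suppressWarnings(as.integer(seed))))
        stop("'seed' is mandatory and must be an integer")
    cfg <- as.list(environment())
    cfg$seed <- as.integer(seed)
    for (f in c("detectionProb", "decoyFrac", "contaminantRate"))
        if (cfg[[f]] < 0 || cfg[[f]] > 1)
            stop("'", f, "' must be in [0, 1]")
    if (cfg$essentialEffect < 0) stop("'essentialEffect' must be >= 0")
    if (length(cfg$baits) < 2L || anyDuplicated(cfg$baits))
        stop("need at least two distinct baits")
    if (cfg$nHuModulated > cfg$nCommon)
        stop("'nHuModulated' cannot exceed 'nCommon'")
    if (cfg$noiseless) {
        cfg$detectionProb <- 1; cfg$decoyFrac <- 0
    }
    structure(cfg, class = "GeneratorConfig")
}

.preyId <- function(i) sprintf("PREY%04d", i)

.plantMembership <- function(cfg) {
    baits <- cfg$baits
    nb <- length(baits)
    # complex signatures follow the BCDX2 / CX3 split of the first five baits
    bcdx2 <- baits[seq_len(min(4L, nb - 1L))]
    cx3 <- c(baits[2L], baits[nb])          # shared subunit + last bait
    total <- cfg$nCommon + cfg$nBcdx2 + cfg$nCx3 +
        nb * cfg$nBaitSpecific + cfg$nBackground
    preys <- .preyId(seq_len(total))
    category <- character(total)
    membership <- vector("list", total)
    i <- 0L
    take <- function(n) { idx <- i + seq_len(n); i <<- i + n; idx }
    idx <- take(cfg$nCommon)
    category[idx] <- "all-common"; membership[idx] <- list(baits)
    idx <- take(cfg$nBcdx2)
    category[idx] <- "BCDX2-exclusive"; membership[idx] <- list(bcdx2)
    idx <- take(cfg$nCx3)
    category[idx] <- "CX3-exclusive"; membership[idx] <- list(cx3)
    for (b in baits) {
        idx <- take(cfg$nBaitSpecific)
        category[idx] <- "bait-specific"; membership[idx] <- list(b)
    }
    idx <- take(cfg$nBackground)
    category[idx] <- "background"
    for (j in idx) {
        repeat {
            m <- sort(sample(baits, sample(1:3, 1L)))
            if (!identical(m, sort(cx3))) break
        }
        membership[[j]] <- m
    }
    names(category) <- names(membership) <- preys
    list(preys = preys, category = category, membership = membership,
         bcdx2 = bcdx2, cx3 = cx3)
}

#' Generate synthetic BioID prey tables with recorded truth
#'
#' Emits one prey-record table covering every bait in both conditions, plus
#' the ground truth needed to score every downstream stage: per-prey complex
#' category and bait membership, HU-modulated preys with their true log2
#' effects, injected contaminant and decoy rows, per-prey protein lengths
#' and spectral means.
#'
#' Complex-member preys appear in exactly their defining baits' tables
#' (subject to `detectionProb`); spectral counts are averages of
#' negative-binomial replicate draws (in noiseless mode, the exact per-prey
#' mean); HU shifts the means of modulated preys by `huLog2Effect`;
#' contaminant rows are drawn from [defaultContaminants()] and decoy rows
#' carry iProphet probability below 0.9.
#'
#' @param config a [generatorConfig()].
#' @return list with `records` (prey-record data.frame as from
#'   [readPreyTable()]) and `truth`.
#' @export
generateBioID <- function(config) {
    stopifnot(inherits(config, "GeneratorConfig"))
    set.seed(config$seed)
    plant <- .plantMembership(config)
    preys <- plant$preys
    lengths <- setNames(sample(100:2000, length(preys), replace = TRUE),
                        preys)
    baseMu <- setNames(rlnorm(length(preys), log(config$countMean), 0.5),
                       preys)
    huMod <- sort(sample(preys[plant$category == "all-common"],
                         config$nHuModulated))
    huEffect <- setNames(rep(2^config$huLog2Effect, length(huMod)), huMod)

    contamSyms <- c("AHNAK", "PRKDC", "TOP1", "HLCS", "FLNB", "PRKAA1",
                    "PRKAA2", "LYZ", "ACACA", "ACACB", "PC", "PCCA",
                    "KRT8", "KRT18", "KRT1", "RPL3", "RPL7", "RPS6", "RPS3")
    rows <- list()
    for (b in config$baits) {
        members <- preys[vapply(plant$membership,
                                function(m) b %in% m, logical(1))]
        for (cond in c("untreated", "HU")) {
            detected <- members[runif(length(members)) <= config$detectionProb]
            mu <- baseMu[detected]
            if (cond == "HU") {
                shift <- intersect(detected, huMod)
                mu[shift] <- mu[shift] * huEffect[shift]
            }
            avg <- if (config$noiseless) mu else
                vapply(mu, function(mm) {
                    mean(rnbinom(config$nReplicates, mu = mm,
                                 size = config$countDispersion))
                }, numeric(1))
            tab <- data.frame(
                bait = b, condition = cond, prey = detected,
                avgSpec = unname(avg),
                uniquePeptides = 1L + rpois(length(detected), 2),
                iProphetProb = round(runif(length(detected), 0.92, 1), 4),
                lengthAA = unname(lengths[detected]),
                nReps = config$nReplicates, stringsAsFactors = FALSE)
            nContam <- round(config$contaminantRate * nrow(tab))
            if (nContam > 0) {
                cs <- sample(contamSyms, min(nContam, length(contamSyms)))
                tab <- rbind(tab, data.frame(
                    bait = b, condition = cond, prey = cs,
                    avgSpec = round(rlnorm(length(cs), log(20), 0.5), 1),
                    uniquePeptides = 1L + rpois(length(cs), 3),
                    iProphetProb = round(runif(length(cs), 0.95, 1), 4),
                    lengthAA = sample(200:2500, length(cs)),
                    nReps = config$nReplicates, stringsAsFactors = FALSE))
            }
            nDecoy <- round(config$decoyFrac * nrow(tab))
            if (nDecoy > 0) {
                ds <- sprintf("DECOY%03d", sample(1:999, nDecoy))
                failMode <- runif(nDecoy) < 0.5
                tab <- rbind(tab, data.frame(
                    bait = b, condition = cond, prey = ds,
                    avgSpec = round(rlnorm(nDecoy, log(3), 0.5), 1),
                    uniquePeptides = ifelse(failMode,
                                            1L + rpois(nDecoy, 1), 0L),
                    iProphetProb = round(ifelse(failMode,
                                                runif(nDecoy, 0, 0.89),
                                                runif(nDecoy, 0.9, 1)), 4),
                    lengthAA = sample(100:2000, nDecoy, replace = TRUE),
                    nReps = config$nReplicates, stringsAsFactors = FALSE))
            }
            rows[[paste(b, cond)]] <- tab
        }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    truth <- list(
        seed = config$seed,
        category = plant$category,
        membership = plant$membership,
        bcdx2Baits = plant$bcdx2, cx3Baits = plant$cx3,
        allCommon = preys[plant$category == "all-common"],
        bcdx2Exclusive = preys[plant$category == "BCDX2-exclusive"],
        cx3Exclusive = preys[plant$category == "CX3-exclusive"],
        huModulated = huMod, huEffect = huEffect,
        lengths = lengths, baseMu = baseMu,
        contaminantSymbols = contamSyms)
    list(records = records, truth = truth)
}

#' Generate a synthetic dropout screen (guide counts) with planted essentials
#'
#' Day-0 guide counts are negative binomial around `screenCountMean`; day-14
#' counts are negative binomial around the day-0 expectation multiplied by
#' the gene's fitness (planted essentials: `essentialEffect`; neutral genes:
#' 1).
#'
#' @param config a [generatorConfig()].
#' @return list with `guides` (data.frame guide/gene/replicate/d0/d14) and
#'   `truth` (`essentials`, `fitness`).
#' @export
generateScreen <- function(config) {
    stopifnot(inherits(config, "GeneratorConfig"))
    set.seed(config$seed + 1L)
    genes <- sprintf("SGENE%04d", seq_len(config$screenGenes))
    essentials <- sort(sample(genes, config$nEssentials))
    fitness <- setNames(rep(1, length(genes)), genes)
    fitness[essentials] <- config$essentialEffect
    guides <- expand.grid(g = seq_len(config$guidesPerGene), gene = genes,
                          replicate = sprintf("R%d",
                                              seq_len(config$screenReplicates)),
                          stringsAsFactors = FALSE)
    guides$guide <- sprintf("%s_g%d", guides$gene, guides$g)
    n <- nrow(guides)
    guides$d0 <- rnbinom(n, mu = config$screenCountMean,
                         size = config$screenCountDispersion)
    guides$d14 <- rnbinom(n, mu = config$screenCountMean *
                              fitness[guides$gene],
                          size = config$screenCountDispersion)
    guides <- guides[, c("guide", "gene", "replicate", "d0", "d14")]
    list(guides = guides,
         truth = list(seed = config$seed, essentials = essentials,
                      fitness = fitness))
}

#' Generate a synthetic NormZ screen profile with planted chemogenomic effects
#'
#' Builds the gene-by-screen NormZ matrix the integrative analyses consume:
#' three olaparib screens (RPE1-hTERT, HeLa, SUM149PT), one RPE1 essentiality
#' screen, one chronic-HU screen and three genotoxic-drug screens. Planted
#' sensitizers score below -1.5 in at least two olaparib screens; planted
#' profile-essential genes score below -2 in the essentiality screen; the
#' HU-modulated preys of `bioidTruth` score above 2 in absolute value in the
#' chronic-HU screen. Background cells are standard normal, or bounded in
#' (-1.5, 1.5) in noiseless mode so threshold recoveries are exact; a small
#' fraction of background cells is missing unless noiseless.
#'
#' @param config a [generatorConfig()].
#' @param bioidTruth the `truth` element of [generateBioID()] run on the
#'   same config.
#' @return list with `profile` (a [ScreenProfile]) and `truth`
#'   (`sensitizers`, `profileEssentials`, `huHits`, screen ids).
#' @export
generateNormZProfile <- function(config, bioidTruth) {
    stopifnot(inherits(config, "GeneratorConfig"))
    set.seed(config$seed + 2L)
    genes <- c(names(bioidTruth$category), config$baits)
    screens <- c("olaparib_RPE1", "olaparib_HeLa", "olaparib_SUM149PT",
                 "essential_RPE1", "HU_chronic",
                 "cisplatin_RPE1", "CPT_RPE1", "IR_RPE1")
    ng <- length(genes)
    m <- matrix(if (config$noiseless) runif(ng * length(screens), -1.5, 1.5)
                else rnorm(ng * length(screens)),
                ng, length(screens), dimnames = list(genes, screens))
    olap <- screens[1:3]
    sens <- sort(sample(bioidTruth$bcdx2Exclusive,
                        round(0.6 * length(bioidTruth$bcdx2Exclusive))))
    for (g in sens) {
        hit <- sample(olap, sample(2:3, 1L))
        m[g, hit] <- runif(length(hit), -3.5, -1.5)
    }
    profEss <- sort(sample(bioidTruth$allCommon,
                           round(0.3 * length(bioidTruth$allCommon))))
    m[profEss, "essential_RPE1"] <- runif(length(profEss), -4, -2)
    huHits <- bioidTruth$huModulated
    m[huHits, "HU_chronic"] <- sample(c(-1, 1), length(huHits),
                                      replace = TRUE) *
        runif(length(huHits), 2.5, 4)
    if (!config$noiseless) {
        planted <- unique(c(sens, profEss, huHits, config$baits))
        candidates <- which(!(rownames(m)[row(m)] %in% planted))
        drop <- sample(candidates, round(0.05 * length(candidates)))
        m[drop] <- NA_real_
    }
    info <- data.frame(
        drug = c("olaparib", "olaparib", "olaparib", "none", "hydroxyurea",
                 "cisplatin", "camptothecin", "ionizing radiation"),
        cellLine = c("RPE1-hTERT", "HeLa", "SUM149PT", "RPE1-hTERT",
                     "RPE1-hTERT", "RPE1-hTERT", "RPE1-hTERT", "RPE1-hTERT"),
        source = "synthetic", row.names = screens)
    list(profile = ScreenProfile(m, info),
         truth = list(seed = config$seed, sensitizers = sens,
                      profileEssentials = profEss, huHits = huHits,
                      olaparibScreens = olap, essentialScreen = "essential_RPE1",
                      huScreen = "HU_chronic"))
}

#' Generate a synthetic survival cohort with planted prognostic genes
#'
#' Patient expression is log-normal; survival time is exponential with the
#' baseline hazard multiplied by `hazardRatio` for each planted hazardous
#' gene whose expression exceeds the cohort median; censoring is independent
#' exponential plus administrative cut-off at `followUpMax` months.
#'
#' @param config a [generatorConfig()].
#' @param genes gene symbols for the expression matrix (default
#'   `GENE0001...`).
#' @return list with `cohort` (a [SurvivalCohort]) and `truth`
#'   (`hazardous`, `hazardRatio`).
#' @export
generateCohort <- function(config, genes = NULL) {
    stopifnot(inherits(config, "GeneratorConfig"))
    set.seed(config$seed + 3L)
    if (is.null(genes))
        genes <- sprintf("GENE%04d", seq_len(config$cohortGenes))
    n <- config$cohortSize
    expr <- matrix(rlnorm(n * length(genes)), n, length(genes),
                   dimnames = list(sprintf("P%04d", seq_len(n)), genes))
    hazardous <- sort(sample(genes, config$nHazardous))
    hazard <- rep(config$baselineHazard, n)
    for (g in hazardous)
        hazard <- hazard * ifelse(expr[, g] > median(expr[, g]),
                                  config$hazardRatio, 1)
    tEvent <- rexp(n, rate = hazard)
    tCens <- pmin(rexp(n, rate = config$censorHazard), config$followUpMax)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    time[time <= 0] <- 1e-6
    cohort <- SurvivalCohort(time, event, expr, endpoint = "OS")
    list(cohort = cohort,
         truth = list(seed = config$seed, hazardous = hazardous,
                      hazardRatio = config$hazardRatio))
}

#' Write a complete synthetic fixture directory
#'
#' Materialises every pipeline input as plain-text files: steady-state and
#' HU prey tables, guide counts, a long-format NormZ table, a GMT collection
#' (with one term per planted complex category plus random terms), a
#' known-interaction edge table covering a planted fraction of each bait's
#' preys, a survival cohort table and the ground truth as JSON.
#'
#' @param config a [generatorConfig()].
#' @param dir output directory (created if needed).
#' @param knownFraction fraction of each bait's preys given a curated
#'   (bait, prey) edge in the known-interaction table.
#' @return invisibly, a named list of the written paths plus the generated
#'   objects (`bioid`, `screen`, `profile`, `cohort`).
#' @export
writeFixtureDirectory <- function(config, dir, knownFraction = 0.1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    bio <- generateBioID(config)
    scr <- generateScreen(config)
    prof <- generateNormZProfile(config, bio$truth)
    coh <- generateCohort(config)
    paths <- list(
        preysUntreated = file.path(dir, "preys_untreated.tsv"),
        preysHU = file.path(dir, "preys_HU.tsv"),
        guideCounts = file.path(dir, "guide_counts.tsv"),
        normZ = file.path(dir, "normz.tsv"),
        gmt = file.path(dir, "sets.gmt"),
        knownEdges = file.path(dir, "known_edges.tsv"),
        cohort = file.path(dir, "cohort.tsv"),
        truth = file.path(dir, "truth.json"))
    writePreyTable(bio$records[bio$records$condition == "untreated", ],
                   paths$preysUntreated)
    writePreyTable(bio$records[bio$records$condition == "HU", ],
                   paths$preysHU)
    write.table(scr$guides, paths$guideCounts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    m <- normZ(prof$profile)
    long <- data.frame(gene = rownames(m)[row(m)],
                       screen = colnames(m)[col(m)],
                       normZ = as.vector(m))
    long <- long[!is.na(long$normZ), ]
    write.table(long, paths$normZ, sep = "\t", quote = FALSE,
                row.names = FALSE)

    set.seed(config$seed + 4L)
    universe <- names(bio$truth$category)
    sets <- list(CPLX_ALLCOMMON = bio$truth$allCommon,
                 CPLX_BCDX2 = bio$truth$bcdx2Exclusive,
                 CPLX_CX3 = bio$truth$cx3Exclusive)
    maxSet <- max(2L, min(120L, length(universe) %/% 2L))
    for (i in 1:12)
        sets[[sprintf("RANDSET%02d", i)]] <-
            sort(sample(universe, sample(seq(2L, maxSet), 1L)))
    gmt <- structure(list(sets = sets,
                          termNames = setNames(paste("synthetic set",
                                                     names(sets)),
                                               names(sets)),
                          source = "synthetic"),
                     class = "GeneSetCollection")
    writeGMT(gmt, paths$gmt)

    edges <- do.call(rbind, lapply(config$baits, function(b) {
        members <- universe[vapply(bio$truth$membership,
                                   function(mm) b %in% mm, logical(1))]
        known <- sample(members, round(knownFraction * length(members)))
        if (!length(known)) return(NULL)
        data.frame(a = b, b = known, stringsAsFactors = FALSE)
    }))
    write.table(edges, paths$knownEdges, sep = "\t", quote = FALSE,
                row.names = FALSE)

    cohDF <- data.frame(patient = rownames(coh$cohort@expression),
                        time = coh$cohort@time, event = coh$cohort@event,
                        coh$cohort@expression, check.names = FALSE)
    write.table(cohDF, paths$cohort, sep = "\t", quote = FALSE,
                row.names = FALSE)

    truth <- list(bioid = bio$truth[c("seed", "allCommon", "bcdx2Exclusive",
                                      "cx3Exclusive", "huModulated")],
                  screen = scr$truth["essentials"],
                  profile = prof$truth[c("sensitizers", "profileEssentials",
                                         "huHits")],
                  cohort = coh$truth)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, list(bioid = bio, screen = scr, profile = prof,
                            cohort = coh)))
}

#' Read a cohort TSV written by [writeFixtureDirectory()]
#'
#' @param path TSV with columns `patient`, `time`, `event` and one column
#'   per gene.
#' @param endpoint endpoint tag.
#' @return a [SurvivalCohort].
#' @export
readCohortTable <- function(path, endpoint = "OS") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    need <- c("patient", "time", "event")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("missing required column(s): ", paste(miss, collapse = ", "))
    expr <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
    rownames(expr) <- df$patient
    SurvivalCohort(df$time, df$event, expr, endpoint)
}
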