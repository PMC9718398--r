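.md5 <- function(paths) {
    paths <- unlist(paths, use.names = FALSE)
    ok <- file.exists(paths)
    h <- rep(NA_character_, length(paths))
    h[ok] <- unname(tools::md5sum(paths[ok]))
    setNames(h, paths)
}

.KNOWN_KEYS <- c("seed", "outDir", "stages", "inputs", "filters", "sets",
                 "screens", "enrichment", "survival", "generator")
.STAGES <- c("simulate", "ingest", "sets", "abundance", "screens",
             "enrich", "survival", "network")

#' Run the proximity-interactome pipeline from a config file
#'
#' Executes the enabled stages in order — simulate, ingest, sets, abundance,
#' screens, enrich, survival, network — writing each stage's outputs under a
#' run directory and finishing with a JSON run manifest (config digest, input
#' digests, seed, package version, output inventory with md5 checksums)
#' sufficient to reproduce the run bit-identically.
#'
#' The YAML config supports keys: `seed` (mandatory), `outDir`, `stages`
#' (subset of the stage names above), `inputs` (paths: `preysUntreated`,
#' `preysHU`, `guideCounts`, `normZ`, `gmt`, `knownEdges`, `cohort`),
#' `filters` (`minProb`, `minUnique`), `screens` (`olaparib` ids,
#' `sensThreshold`, `minScreens`, `essentialScreen`, `essThreshold`,
#' `huScreen`, `fcCut`, `zCut`, `clusterK`), `survival` (`cutoffMode`,
#' `alpha`) and `generator` (overrides passed to [generatorConfig()]).
#' With the `simulate` stage enabled, any input not given explicitly is
#' taken from the generated fixture directory.
#'
#' @param configPath path to the YAML config (or an equivalent named list).
#' @param outDir output directory; overrides the config's `outDir`.
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
runPipeline <- function(configPath, outDir = NULL) {
    if (is.character(configPath)) {
        if (!file.exists(configPath))
            stop("config file not found: ", configPath)
        cfg <- yaml::read_yaml(configPath)
        cfgDigest <- unname(tools::md5sum(configPath))
    } else {
        cfg <- configPath
        tmp <- tempfile(fileext = ".yaml")
        yaml::write_yaml(cfg, tmp)
        cfgDigest <- unname(tools::md5sum(tmp))
        unlink(tmp)
    }
    unknown <- setdiff(names(cfg), .KNOWN_KEYS)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (is.null(cfg$seed)) stop("config key 'seed' is required")
    stages <- cfg$stages %||% .STAGES
    badStage <- setdiff(stages, .STAGES)
    if (length(badStage))
        stop("unknown stage(s) in config key 'stages': ",
             paste(badStage, collapse = ", "))
    outDir <- outDir %||% cfg$outDir %||% stop("config key 'outDir' required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    inputs <- cfg$inputs %||% list()
    outputs <- character()
    emit <- function(df, name) {
        p <- file.path(outDir, name)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <<- c(outputs, p)
        p
    }

    if ("simulate" %in% stages) {
        gcArgs <- cfg$generator %||% list()
        gcArgs$seed <- cfg$seed
        gcfg <- do.call(generatorConfig, gcArgs)
        fx <- writeFixtureDirectory(gcfg, file.path(outDir, "fixture"))
        fileKeys <- c("preysUntreated", "preysHU", "guideCounts", "normZ",
                      "gmt", "knownEdges", "cohort")
        for (k in fileKeys)
            if (is.null(inputs[[k]])) inputs[[k]] <- fx[[k]]
        outputs <- c(outputs, unlist(fx[fileKeys], use.names = FALSE),
                     fx$truth)
    }
    for (k in names(inputs))
        if (!file.exists(inputs[[k]]))
            stop("input path does not exist: ", inputs[[k]],
                 " (config key inputs$", k, ")")

    interactomes <- interactomesHU <- NULL
    filtered <- NULL
    if ("ingest" %in% stages) {
        flt <- cfg$filters %||% list()
        recs <- rbind(readPreyTable(inputs$preysUntreated),
                      if (!is.null(inputs$preysHU))
                          readPreyTable(inputs$preysHU))
        filtered <- filterPreys(recs,
                                minProb = flt$minProb %||% 0.9,
                                minUnique = flt$minUnique %||% 1L)
        emit(filtered, "filtered_preys.tsv")
        rp <- file.path(outDir, "filter_report.json")
        jsonlite::write_json(attr(filtered, "filterReport"), rp,
                             auto_unbox = TRUE)
        outputs <- c(outputs, rp)
        interactomes <- buildInteractomes(filtered, "untreated")
        if (any(filtered$condition == "HU"))
            interactomesHU <- buildInteractomes(filtered, "HU")
    }

    if ("sets" %in% stages) {
        if (is.null(interactomes)) stop("'sets' stage requires 'ingest'")
        specs <- list(all_common = allCommonSpec(),
                      bcdx2_exclusive = bcdx2Spec(),
                      cx3_exclusive = cx3Spec())
        for (nm in names(specs)) {
            g <- intersectPreys(interactomes, specs[[nm]])
            emit(data.frame(prey = g,
                            signature = paste(specs[[nm]]$include,
                                              collapse = "&")),
                 paste0("set_", nm, ".tsv"))
        }
        cells <- upsetDecompose(interactomes)
        emit(attr(cells, "cellSizes"), "upset_cells.tsv")
        if (!is.null(inputs$knownEdges)) {
            known <- readEdgeTable(inputs$knownEdges)
            nov <- do.call(rbind, lapply(interactomes, function(it) {
                r <- noveltyReport(it, known)
                data.frame(bait = bait(it), nPreys = length(preyNames(it)),
                           nKnown = length(r$known), nNovel = length(r$novel),
                           foldOverKnown = r$foldOverKnown)
            }))
            emit(nov, "novelty.tsv")
        }
    }

    diffAll <- NULL
    if ("abundance" %in% stages) {
        if (is.null(interactomes)) stop("'abundance' stage requires 'ingest'")
        lengths <- setNames(filtered$lengthAA, filtered$prey)
        lengths <- lengths[!duplicated(names(lengths))]
        se <- buildAbundanceMatrix(c(interactomes, interactomesHU), lengths)
        m <- flooredLog2SAF(se)
        emit(data.frame(prey = rownames(m), m, check.names = FALSE),
             "abundance_log2saf.tsv")
        if (!is.null(interactomesHU)) {
            shared <- intersect(names(interactomes), names(interactomesHU))
            diffAll <- do.call(rbind, lapply(shared, function(b)
                differentialHU(interactomes[[b]], interactomesHU[[b]])))
            emit(diffAll, "differential_hu.tsv")
        }
    }

    profile <- NULL
    if ("screens" %in% stages) {
        sc <- cfg$screens %||% list()
        if (!is.null(inputs$guideCounts)) {
            nz <- rankEssentiality(readGuideCounts(inputs$guideCounts))
            emit(data.frame(gene = names(nz), normZ = unname(nz)),
                 "essentiality_normz.tsv")
        }
        if (!is.null(inputs$normZ)) {
            profile <- readNormZTable(inputs$normZ)
            olap <- sc$olaparib %||% grep("olaparib", screenIds(profile),
                                          value = TRUE)
            if (length(olap)) {
                sens <- classifySensitizers(
                    profile, olap, threshold = sc$sensThreshold %||% -1,
                    minScreens = sc$minScreens %||% 2L)
                emit(data.frame(gene = sens,
                                rule = sprintf("normZ<%s in >=%d of {%s}",
                                               sc$sensThreshold %||% -1,
                                               sc$minScreens %||% 2L,
                                               paste(olap, collapse = ","))),
                     "sensitizers.tsv")
            }
            essScreen <- sc$essentialScreen %||%
                grep("essential", screenIds(profile), value = TRUE)[1]
            if (!is.na(essScreen)) {
                ess <- classifyEssentials(profile, essScreen,
                                          threshold = sc$essThreshold %||% -1.5)
                emit(data.frame(gene = ess,
                                rule = sprintf("normZ<%s in %s",
                                               sc$essThreshold %||% -1.5,
                                               essScreen)),
                     "essentials.tsv")
            }
            huScreen <- sc$huScreen %||%
                grep("HU", screenIds(profile), value = TRUE)[1]
            if (!is.null(diffAll) && !is.na(huScreen)) {
                hits <- differentialHUHits(diffAll, profile, huScreen,
                                           fcCut = sc$fcCut %||% 1,
                                           zCut = sc$zCut %||% 2)
                emit(data.frame(gene = hits,
                                rule = sprintf("|log2FC|>%s & |normZ|>%s",
                                               sc$fcCut %||% 1,
                                               sc$zCut %||% 2)),
                     "hu_hits.tsv")
            }
            k <- sc$clusterK %||% 4L
            if (nrow(normZ(profile)) >= k) {
                cl <- clusterProfiles(profile, k = k, missing = "zero")
                emit(data.frame(gene = names(clusterIds(cl)),
                                cluster = unname(clusterIds(cl)),
                                leafPosition = match(names(clusterIds(cl)),
                                                     leafOrder(cl))),
                     "clusters.tsv")
            }
        }
    }

    if ("enrich" %in% stages && !is.null(inputs$gmt)) {
        if (is.null(interactomes)) stop("'enrich' stage requires 'ingest'")
        gmt <- readGMT(inputs$gmt)
        universe <- unique(filtered$prey)
        query <- intersectPreys(interactomes, allCommonSpec())
        res <- suppressWarnings(ora(query, gmt, universe = universe))
        emit(res, "enrichment_all_common.tsv")
        emit(enrichmentDotPlot(res, alpha = 0.05), "enrichment_dotplot.tsv")
    }

    if ("survival" %in% stages && !is.null(inputs$cohort)) {
        sv <- cfg$survival %||% list()
        cohort <- readCohortTable(inputs$cohort)
        res <- screenGenes(cohort,
                           cutoffMode = sv$cutoffMode %||% "median",
                           alpha = sv$alpha %||% 0.05)
        emit(res, "survival_screen.tsv")
    }

    if ("network" %in% stages) {
        if (is.null(interactomes)) stop("'network' stage requires 'ingest'")
        net <- buildNetwork(interactomes)
        if (!is.null(inputs$knownEdges))
            net <- augmentNetwork(net,
                                  list(known = readEdgeTable(inputs$knownEdges)))
        gp <- file.path(outDir, "network.graphml")
        writeNetwork(net, graphml = gp,
                     edgeList = file.path(outDir, "network_edges.tsv"))
        outputs <- c(outputs, gp, file.path(outDir, "network_edges.tsv"))
    }

    manifest <- list(
        package = as.character(utils::packageVersion("proxitome")),
        seed = cfg$seed,
        configDigest = cfgDigest,
        stages = stages,
        inputDigests = as.list(.md5(inputs)),
        outputs = as.list(.md5(unique(outputs))))
    mp <- file.path(outDir, "manifest.json")
    tmp <- paste0(mp, ".tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, mp)   # atomic manifest write
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
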