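#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds for [runPipeline()]. All
#' thresholds default to the study's values: |log2FC| > 1 and adjusted
#' p < 0.05 for differential entities, duplex energy <= -20 kcal/mol,
#' methylation difference >= 25 points at q < 0.01 with coverage >= 10,
#' promoter = 2000 bp upstream of the TSS, and a 1000-iteration
#' permutation test.
#'
#' @param annotation GFF3 path.
#' @param geneCounts,mirnaCounts count TSV paths.
#' @param sampleSheet sample sheet TSV path.
#' @param predictionsA,predictionsB prediction TSV paths.
#' @param methFiles named character vector of per-sample CpG TSVs (names
#'   are sample ids).
#' @param functionalList functional gene list TSV path (columns gene_id,
#'   symbol, pathway).
#' @param outDir output directory for reports.
#' @param lfcMin,alpha differential-expression thresholds.
#' @param energyMax duplex-energy threshold (kcal/mol).
#' @param diffMin,qMax,minCoverage differential-methylation thresholds.
#' @param upstream promoter size in bp.
#' @param promoterStrandAware honour transcription orientation for
#'   promoters.
#' @param iterations,permSeed permutation-test settings.
#' @param cohort regulation-mode cohort: \code{"de"} or
#'   \code{"functional"} (see [classifyRegulation()]).
#' @param universe permutation universe: \code{"functional"} or
#'   \code{"all"} annotated genes.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(annotation, geneCounts, mirnaCounts,
                           sampleSheet, predictionsA, predictionsB,
                           methFiles, functionalList, outDir,
                           lfcMin = 1.0, alpha = 0.05, energyMax = -20,
                           diffMin = 25, qMax = 0.01, minCoverage = 10,
                           upstream = 2000, promoterStrandAware = TRUE,
                           iterations = 1000, permSeed = 1,
                           cohort = "de", universe = "functional") {
    structure(as.list(environment()), class = "PipelineConfig")
}

.paramList <- function(config) {
    config[c("lfcMin", "alpha", "energyMax", "diffMin", "qMax",
             "minCoverage", "upstream", "promoterStrandAware",
             "iterations", "permSeed", "cohort", "universe")]
}

#' Run the integrative analysis on in-memory inputs
#'
#' The orchestration core behind [runPipeline()], also usable directly on
#' a [generateBundle()] result: differential expression for genes and
#' miRNAs over the design's contrasts, target-pair construction
#' (two-tool intersection, region assignment, expression correlation),
#' per-contrast differential methylation and DMSG construction,
#' regulation-mode classification per time point, the dual-regulation
#' permutation test, structural-complementarity comparisons, and the
#' |log2FC| group contrasts.
#'
#' @param catalog a [GeneCatalog-class].
#' @param geneCounts,mirnaCounts entities x samples count matrices.
#' @param sheet sample sheet data.frame.
#' @param predsA,predsB prediction data.frames.
#' @param methTables named list of per-sample CpG data.frames.
#' @param functional functional gene list data.frame (gene_id, symbol,
#'   pathway).
#' @param params list of thresholds as in [pipelineConfig()] (defaults
#'   used for any omitted entry).
#' @param onStage optional callback invoked with each stage name
#'   (annotation-consuming stages run in order differential, targeting,
#'   methylome, integration); used for progress logging and failure
#'   attribution.
#' @return list with elements \code{gene_stats}, \code{mirna_stats},
#'   \code{de_genes_by_contrast}, \code{de_mirnas_by_contrast},
#'   \code{pairs}, \code{region_distribution}, \code{diff_sites},
#'   \code{dmsgs}, \code{regulation_calls}, \code{mode_proportions},
#'   \code{permutation}, \code{complementarity}, \code{lfc_groups},
#'   \code{mutual_regulation}.
#' @export
runIntegration <- function(catalog, geneCounts, mirnaCounts, sheet,
                           predsA, predsB, methTables, functional,
                           params = list(), onStage = NULL) {
    defaults <- .paramList(pipelineConfig(
        annotation = "", geneCounts = "", mirnaCounts = "",
        sampleSheet = "", predictionsA = "", predictionsB = "",
        methFiles = character(0), functionalList = "", outDir = ""))
    params <- utils::modifyList(defaults, params)
    stage <- function(s) if (!is.null(onStage)) onStage(s)
    times <- sort(unique(sheet$time_h))
    contrasts <- defaultContrasts(times)
    ckey <- vapply(contrasts, function(ct) paste0(ct[1], "vs", ct[2]),
                   character(1))

    ## differential expression
    stage("differential")
    geneStats <- differentialStats(geneCounts, sheet, contrasts)
    mirnaStats <- differentialStats(mirnaCounts, sheet, contrasts)
    degs <- callDifferential(geneStats, params$lfcMin, params$alpha)
    demir <- callDifferential(mirnaStats, params$lfcMin, params$alpha)
    deG <- stats::setNames(lapply(contrasts, function(ct)
        differentialAt(degs, ct[1], ct[2])), ckey)
    deM <- stats::setNames(lapply(contrasts, function(ct)
        differentialAt(demir, ct[1], ct[2])), ckey)

    ## target pairs
    stage("targeting")
    pairs <- intersectPredictions(predsA, predsB, params$energyMax)
    if (nrow(pairs)) {
        pairs <- assignPairRegions(pairs, catalog)
        gProf <- timeProfiles(geneCounts, sheet)
        mProf <- timeProfiles(mirnaCounts, sheet)
        pairs <- attachCorrelation(pairs, mProf, gProf)
        g <- geneRanges(catalog)
        pairs$symbol <- mcols(g)$symbol[match(pairs$gene_id, names(g))]
    } else {
        gProf <- timeProfiles(geneCounts, sheet)
    }
    regionDist <- bindingRegionDistribution(pairs)

    ## methylation
    stage("methylome")
    calls <- methylationCallsFromTables(methTables, sheet,
                                        minCoverage = params$minCoverage)
    diffSites <- list()
    dmsgs <- list()
    for (i in seq_along(contrasts)) {
        ct <- contrasts[[i]]
        gA <- sheet$sample_id[sheet$time_h == ct[1]]
        gB <- sheet$sample_id[sheet$time_h == ct[2]]
        ds <- diffMethylation(calls, gA, gB, params$diffMin, params$qMax)
        dm <- buildDmsgs(ds, catalog, functional,
                         upstream = params$upstream,
                         strandAware = params$promoterStrandAware)
        if (nrow(dm)) {
            dm$correlation_sign <- vapply(seq_len(nrow(dm)), function(r) {
                idx <- which(
                    as.character(seqnames(
                        SummarizedExperiment::rowRanges(calls))) ==
                        dm$chrom[r] &
                    start(SummarizedExperiment::rowRanges(calls)) ==
                        dm$pos[r])
                tryCatch(methylationExpressionDirection(
                    siteMethylationProfile(calls, idx),
                    gProf[dm$gene_id[r], ]),
                    error = function(e) NA_character_)
            }, character(1))
            dm$contrast <- ckey[i]
        }
        diffSites[[ckey[i]]] <- ds
        dmsgs[[ckey[i]]] <- dm
    }

    ## per-time regulation modes
    stage("integration")
    funGenes <- functional$gene_id
    callRows <- list()
    propRows <- list()
    lfcRows <- list()
    for (t in setdiff(times, 0)) {
        k <- paste0("0vs", t)
        active <- pairsActiveAt(pairs, deM[[k]], deG[[k]])
        cl <- classifyRegulation(t, deG[[k]], active, dmsgs[[k]],
                                 funGenes, cohort = params$cohort)
        callRows[[k]] <- cl
        pp <- modeProportions(cl)
        propRows[[k]] <- data.frame(time_h = t,
                                    mode = names(pp$counts),
                                    count = as.integer(pp$counts),
                                    proportion = as.numeric(pp$proportions),
                                    n_none = pp$n_none,
                                    stringsAsFactors = FALSE)
        st <- geneStats[geneStats$ref_time == 0 & geneStats$test_time == t, ]
        lfcVec <- stats::setNames(st$log2fc, st$entity_id)
        lc <- lfcGroupComparison(cl, lfcVec)
        lc$time_h <- t
        lfcRows[[k]] <- lc
    }
    regulationCalls <- do.call(rbind, callRows)
    rownames(regulationCalls) <- NULL

    ## dual-regulation permutation test
    allDmsgGenes <- unique(unlist(lapply(dmsgs, function(d) d$gene_id)))
    mirnaGenes <- intersect(funGenes,
                            unique(unlist(lapply(setdiff(times, 0),
        function(t) {
            k <- paste0("0vs", t)
            pairsActiveAt(pairs, deM[[k]], deG[[k]])$gene_id
        }))))
    methGenes <- intersect(funGenes, allDmsgGenes)
    universe <- if (params$universe == "functional") funGenes else
        geneIds(catalog)
    perm <- dualRegulationPermutation(universe, mirnaGenes, methGenes,
                                      iterations = params$iterations,
                                      seed = params$permSeed)

    ## structural complementarity
    targeted <- intersect(funGenes, unique(pairs$gene_id))
    nonTargeted <- setdiff(funGenes, targeted)
    levels <- vapply(times, function(t)
        geneMethylationLevels(calls, catalog,
                              samples = sheet$sample_id[sheet$time_h == t],
                              geneIds = funGenes,
                              upstream = params$upstream,
                              strandAware = params$promoterStrandAware),
        numeric(length(funGenes)))
    colnames(levels) <- as.character(times)
    siteCounts <- geneSiteCounts(calls, catalog, geneIds = funGenes,
                                 upstream = params$upstream,
                                 strandAware = params$promoterStrandAware)
    comp <- structuralComplementarity(targeted, nonTargeted, levels,
                                      siteCounts)

    ## mutual regulation of the machinery genes
    allDmsgs <- do.call(rbind, dmsgs[vapply(dmsgs, nrow, integer(1)) > 0])
    mutual <- mutualRegulationReport(
        pairs, if (is.null(allDmsgs))
            data.frame(symbol = character(0), direction = character(0))
        else allDmsgs)

    list(gene_stats = geneStats, mirna_stats = mirnaStats,
         de_genes_by_contrast = deG, de_mirnas_by_contrast = deM,
         pairs = pairs, region_distribution = regionDist,
         diff_sites = diffSites, dmsgs = dmsgs,
         regulation_calls = regulationCalls,
         mode_proportions = do.call(rbind, propRows),
         permutation = perm,
         complementarity = comp,
         lfc_groups = do.call(rbind, lfcRows),
         mutual_regulation = mutual,
         mirna_genes = mirnaGenes, meth_genes = methGenes)
}

#' Run the full pipeline from files
#'
#' Reads every input, runs [runIntegration()], and writes the report
#' files to the output directory: \code{regulation_calls.tsv},
#' \code{mode_proportions.tsv}, \code{permutation.json} (with the full
#' null distribution), \code{complementarity.tsv},
#' \code{lfc_groups.tsv}, \code{mutual_regulation.tsv}, plus
#' \code{target_pairs.tsv}, \code{dmsgs.tsv} and a machine-readable
#' \code{run_manifest.json}. Deterministic for a fixed config (including
#' the permutation seed); timestamps appear only in the manifest.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the [runIntegration()] result.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    inputs <- c(config$annotation, config$geneCounts, config$mirnaCounts,
                config$sampleSheet, config$predictionsA,
                config$predictionsB, config$functionalList,
                config$methFiles)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("missing input file(s):\n  ",
             paste(missing, collapse = "\n  "))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

    catalog <- loadAnnotation(config$annotation)
    sheet <- readSampleSheet(config$sampleSheet)
    geneCounts <- readCounts(config$geneCounts)
    mirnaCounts <- readCounts(config$mirnaCounts)
    predsA <- readPredictions(config$predictionsA)
    predsB <- readPredictions(config$predictionsB)
    functional <- utils::read.table(config$functionalList, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    methTables <- lapply(config$methFiles, function(p)
        utils::read.table(p, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
    names(methTables) <- names(config$methFiles)

    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    lastStage <- "input"
    res <- tryCatch(
        runIntegration(catalog, geneCounts, mirnaCounts, sheet,
                       predsA, predsB, methTables, functional,
                       params = .paramList(config),
                       onStage = function(s) {
                           lastStage <<- s
                           message("[", s, "] starting")
                       }),
        error = function(e) {
            jsonlite::write_json(
                list(failed_stage = lastStage,
                     error = conditionMessage(e),
                     started = started,
                     config = config[setdiff(names(config),
                                             "methFiles")]),
                file.path(config$outDir, "error_manifest.json"),
                auto_unbox = TRUE, digits = NA, null = "null")
            stop("pipeline failed at stage '", lastStage, "': ",
                 conditionMessage(e), call. = FALSE)
        })

    out <- function(f) file.path(config$outDir, f)
    .writeTsv(res$regulation_calls, out("regulation_calls.tsv"))
    .writeTsv(res$mode_proportions, out("mode_proportions.tsv"))
    .writeTsv(res$lfc_groups, out("lfc_groups.tsv"))
    .writeTsv(res$mutual_regulation, out("mutual_regulation.tsv"))
    .writeTsv(res$pairs, out("target_pairs.tsv"))
    allDmsgs <- do.call(rbind,
                        res$dmsgs[vapply(res$dmsgs, nrow,
                                         integer(1)) > 0])
    if (is.null(allDmsgs)) {
        allDmsgs <- data.frame(gene_id = character(0),
                               symbol = character(0),
                               chrom = character(0), pos = integer(0),
                               location = character(0),
                               meth_diff = numeric(0),
                               direction = character(0),
                               function_label = character(0),
                               correlation_sign = character(0),
                               contrast = character(0))
    }
    rownames(allDmsgs) <- NULL
    .writeTsv(allDmsgs, out("dmsgs.tsv"))
    compLevels <- res$complementarity$levels
    compLevels$comparison <- "methylation_level"
    sc <- res$complementarity$site_counts
    if (!is.null(sc)) {
        sc$time <- NA_character_
        sc$comparison <- "site_count"
        compLevels <- rbind(compLevels, sc[, names(compLevels)])
    }
    .writeTsv(compLevels, out("complementarity.tsv"))
    perm <- res$permutation
    jsonlite::write_json(
        list(universe_size = perm@universeSize, n_mirna = perm@nMirna,
             n_meth = perm@nMeth, observed_overlap = perm@observedOverlap,
             iterations = perm@iterations, seed = perm@seed,
             p_empirical = perm@pEmpirical,
             null_overlaps = perm@nullOverlaps),
        out("permutation.json"), auto_unbox = TRUE, digits = NA)

    manifest <- list(
        package_version = as.character(utils::packageVersion("epistress")),
        started = started,
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = config[setdiff(names(config), "methFiles")],
        input_md5 = as.list(tools::md5sum(inputs)),
        record_counts = list(
            genes = nrow(geneCounts), mirnas = nrow(mirnaCounts),
            samples = nrow(sheet), target_pairs = nrow(res$pairs),
            dmsg_records = nrow(allDmsgs),
            regulation_calls = nrow(res$regulation_calls)))
    jsonlite::write_json(manifest, out("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(res)
}

#' Run the pipeline on a generated bundle written to disk
#'
#' Convenience wrapper: writes the bundle with [writeSimBundle()], builds
#' a [pipelineConfig()] pointing at the files, and runs [runPipeline()].
#'
#' @param bundle a [generateBundle()] result.
#' @param dir working directory for the bundle and reports.
#' @param ... overrides passed to [pipelineConfig()].
#' @return invisibly, the [runIntegration()] result.
#' @export
runPipelineOnBundle <- function(bundle, dir, ...) {
    paths <- writeSimBundle(bundle, dir)
    methFiles <- stats::setNames(
        file.path(dir, "meth", paste0(bundle$sheet$sample_id, ".tsv")),
        bundle$sheet$sample_id)
    config <- pipelineConfig(
        annotation = paths[["annotation"]],
        geneCounts = paths[["gene_counts"]],
        mirnaCounts = paths[["mirna_counts"]],
        sampleSheet = paths[["sample_sheet"]],
        predictionsA = paths[["predictions_a"]],
        predictionsB = paths[["predictions_b"]],
        methFiles = methFiles,
        functionalList = paths[["functional"]],
        outDir = file.path(dir, "reports"), ...)
    runPipeline(config)
}
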