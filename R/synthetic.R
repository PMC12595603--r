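#' Simulation configuration
#'
#' Parameters of the multi-omics simulator. Defaults emulate the
#' repeated-stress study conditions: six sampling times
#' (0/24/48/96/120/144 h) with replicate counts 6/4/6/4/4/3, miRNA
#' dominance among regulated genes, binding sites mostly in the CDS with
#' UTR binding skewed towards negative correlation, baseline methylation
#' near 0.20 with a small depression (about 0.035) in miRNA-targeted
#' genes, and a tunable dual-regulation enrichment factor
#' (\code{rhoDual}) multiplying the odds that a methylation-regulated
#' gene is also miRNA-targeted.
#'
#' @param nGenes,nMirnas numbers of genes and miRNAs.
#' @param chromCount chromosomes genes are spread over.
#' @param times sampling times (hours).
#' @param replicates per-time replicate counts.
#' @param fracFunctional fraction of genes on the functional list.
#' @param pathwayWeights named weights for water/ion/faa labels.
#' @param fracDeGenes probability a non-targeted gene carries a planted
#'   expression response.
#' @param fracDeMirnas fraction of miRNAs differentially expressed.
#' @param lfcEffect mean planted |log2 fold change|.
#' @param nbDispersion negative-binomial dispersion of counts.
#' @param fracTargeted fraction of functional genes with miRNA target
#'   pairs.
#' @param regionWeights binding-region weights (utr5, cds, utr3).
#' @param negCorrFrac per-region probability of a planted negative
#'   miRNA-target correlation.
#' @param cpgPerGene mean CpG sites per gene.
#' @param siteCountDeficit multiplier on \code{cpgPerGene} for
#'   miRNA-targeted genes (fewer methylation-capable sites).
#' @param bbMu baseline methylation level (beta mean).
#' @param bbConcentration concentration of the site-level baseline beta.
#' @param sampleConcentration beta-binomial concentration of per-sample
#'   replicate overdispersion.
#' @param fracDmGenes fraction of functional genes planted with at least
#'   one differentially methylated site.
#' @param fracDmSites probability each additional site of a
#'   methylation-regulated gene is also differential.
#' @param dmShift planted methylation difference, percentage points.
#' @param deltaTargeted depression of baseline methylation level in
#'   targeted genes.
#' @param rhoDual dual-regulation enrichment factor (1 = independence).
#' @param meanCoverage mean per-site sequencing coverage.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nGenes = 500, nMirnas = 60, chromCount = 5,
                      times = c(0, 24, 48, 96, 120, 144),
                      replicates = c(6, 4, 6, 4, 4, 3),
                      fracFunctional = 0.6,
                      pathwayWeights = c(water = 0.05, ion = 0.55,
                                         faa = 0.40),
                      fracDeGenes = 0.3, fracDeMirnas = 0.5,
                      lfcEffect = 2.0, nbDispersion = 0.1,
                      fracTargeted = 0.4,
                      regionWeights = c(utr5 = 0.1, cds = 0.7, utr3 = 0.2),
                      negCorrFrac = c(utr5 = 0.70, cds = 0.42,
                                      utr3 = 0.73),
                      cpgPerGene = 3, siteCountDeficit = 0.85,
                      bbMu = 0.20, bbConcentration = 20,
                      sampleConcentration = 50,
                      fracDmGenes = 0.12, fracDmSites = 0.3,
                      dmShift = 30, deltaTargeted = 0.035,
                      rhoDual = 1, meanCoverage = 30) {
    cfg <- as.list(environment())
    fr <- c(fracFunctional, fracDeGenes, fracDeMirnas, fracTargeted,
            fracDmGenes, fracDmSites)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (abs(sum(regionWeights) - 1) > 1e-8)
        stop("regionWeights must sum to 1")
    if (length(times) != length(replicates))
        stop("times and replicates must align")
    if (rhoDual < 0) stop("rhoDual must be >= 0")
    nF <- round(fracFunctional * nGenes)
    if (round(fracTargeted * nF) > nF || round(fracDmGenes * nF) > nF)
        stop("infeasible set sizes given marginals")
    structure(cfg, class = "SimConfig")
}

#' Plant miRNA- and methylation-regulated gene sets with dual enrichment
#'
#' Samples the miRNA-regulated set uniformly; the overlap of the
#' methylation-regulated set with it is drawn from Fisher's noncentral
#' hypergeometric distribution
#' \eqn{P(k) \propto \binom{n_A}{k}\binom{N-n_A}{n_B-k}\,\omega^k},
#' with the odds parameter \eqn{\omega} solved so that the expected
#' overlap equals \code{rhoDual} times the independence expectation
#' \eqn{n_A n_B / N} -- i.e. \code{rhoDual} is literally the enrichment
#' factor of expected dual regulation over independence. Members are then
#' drawn uniformly inside and outside the miRNA set.
#' \code{rhoDual = 1} recovers independent uniform draws (the null of the
#' permutation test, \eqn{\omega = 1}); \code{rhoDual = 0} forbids
#' overlap; values with \code{rhoDual * nA * nB / N >=} \code{min(nA,
#' nB)} are infeasible.
#'
#' @param functionalGenes character vector: the universe.
#' @param nMirna,nMeth set sizes.
#' @param rhoDual enrichment factor (>= 0).
#' @return list with \code{mirna} and \code{meth} character vectors.
#' @export
plantRegulationSets <- function(functionalGenes, nMirna, nMeth,
                                rhoDual = 1) {
    N <- length(functionalGenes)
    if (nMirna > N || nMeth > N)
        stop("infeasible: set size exceeds universe")
    a <- sample(functionalGenes, nMirna)
    kv <- max(0, nMeth - (N - nMirna)):min(nMirna, nMeth)
    base <- lchoose(nMirna, kv) + lchoose(N - nMirna, nMeth - kv)
    target <- rhoDual * nMirna * nMeth / N
    if (target < min(kv) || (target >= min(nMirna, nMeth) &&
                             length(kv) > 1))
        stop("infeasible rhoDual given marginals")
    nchW <- function(logOmega) {
        lw <- base + kv * logOmega
        w <- exp(lw - max(lw))
        w / sum(w)
    }
    logOmega <- if (rhoDual == 1) 0 else if (rhoDual == 0) -Inf else
        stats::uniroot(function(lo) sum(kv * nchW(lo)) - target,
                       lower = -50, upper = 50, tol = 1e-10)$root
    w <- if (is.finite(logOmega)) nchW(logOmega) else
        as.numeric(kv == min(kv))
    k <- if (length(kv) == 1) kv else sample(kv, 1, prob = w)
    outside <- setdiff(functionalGenes, a)
    b <- c(if (k > 0) sample(a, k),
           if (nMeth - k > 0) sample(outside, nMeth - k))
    list(mirna = a, meth = b)
}

.expandSheet <- function(times, replicates) {
    do.call(rbind, lapply(seq_along(times), function(i) {
        data.frame(
            sample_id = sprintf("T%03d_r%d", times[i],
                                seq_len(replicates[i])),
            time_h = times[i], stage = stageForTime(times[i]),
            replicate = seq_len(replicates[i]),
            stringsAsFactors = FALSE)
    }))
}

# per-time log2fc profile shapes of the repeated-stress design
.profileShapes <- function(times) {
    list(
        sustained = as.numeric(times > 0),
        early = as.numeric(times %in% c(24, 48)),
        late = as.numeric(times >= 96),
        stress_only = as.numeric(times %in% c(24, 48, 120, 144))
    )
}

.rbetaMeanConc <- function(n, mean, conc) {
    stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Generate a synthetic multi-omics bundle
#'
#' Produces, deterministically for a given seed, a complete in-memory
#' bundle with the statistical structure the integrative analysis assumes:
#' a non-overlapping gene layout with 5'UTR/CDS/3'UTR structure, negative
#' binomial gene and miRNA counts with planted per-time log2 fold changes,
#' beta-binomial CpG methylation counts with planted differential sites and
#' a methylation depression in targeted genes, target predictions emitted
#' into both tool files (energies passing the -20 kcal/mol threshold) plus
#' decoys of three kinds (single-tool, weak-energy, shuffled-gene), and
#' truth tables for every planted quantity.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return list of class \code{SimBundle} with elements \code{catalog},
#'   \code{sheet}, \code{geneCounts}, \code{mirnaCounts},
#'   \code{predictionsA}, \code{predictionsB}, \code{methTables},
#'   \code{functional}, \code{truth}, \code{config}, \code{seed}.
#' @seealso [writeSimBundle()], [truthRecoveryReport()]
#' @export
generateBundle <- function(config = simConfig(), seed = 1) {
    stopifnot(inherits(config, "SimConfig"))
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)

    cfg <- config
    times <- cfg$times
    sheet <- .expandSheet(times, cfg$replicates)
    geneIdv <- sprintf("G%04d", seq_len(cfg$nGenes))
    symbols <- sprintf("GENE%04d", seq_len(cfg$nGenes))
    mirnaIdv <- sprintf("mir-%03d", seq_len(cfg$nMirnas))

    ## ---- gene layout -------------------------------------------------
    chrom <- sprintf("chr%d", rep_len(seq_len(cfg$chromCount),
                                      cfg$nGenes))
    l5 <- sample(80:300, cfg$nGenes, replace = TRUE)
    lc <- sample(600:1500, cfg$nGenes, replace = TRUE)
    l3 <- sample(150:500, cfg$nGenes, replace = TRUE)
    gap <- 2500 + sample(0:1500, cfg$nGenes, replace = TRUE)
    strand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
    startv <- integer(cfg$nGenes)
    cursor <- stats::setNames(rep(1L, cfg$chromCount),
                              sprintf("chr%d", seq_len(cfg$chromCount)))
    glen <- l5 + lc + l3
    for (i in seq_len(cfg$nGenes)) {
        startv[i] <- cursor[chrom[i]] + gap[i]
        cursor[chrom[i]] <- startv[i] + glen[i]
    }
    endv <- startv + glen - 1L
    chromLengths <- cursor + 3000

    genes <- GRanges(chrom, IRanges(startv, endv), strand = strand)
    meta <- data.frame(
        gene_id = geneIdv, symbol = symbols,
        tss = ifelse(strand == "-", endv, startv),
        tes = ifelse(strand == "-", startv, endv),
        utr5_len = l5, cds_len = lc, utr3_len = l3,
        transcript_length = glen, stringsAsFactors = FALSE)
    mcols(genes) <- DataFrame(meta)

    # compartment pieces, vectorised: exon spans the gene; on the + strand
    # the genomic order is 5'UTR/CDS/3'UTR, mirrored on the - strand
    firstLen <- ifelse(strand == "+", l5, l3)
    pStart <- cbind(startv, startv, startv + firstLen,
                    startv + firstLen + lc)
    pEnd <- cbind(endv, startv + firstLen - 1L,
                  startv + firstLen + lc - 1L, endv)
    pFeat <- cbind(rep("exon", cfg$nGenes),
                   ifelse(strand == "+", "five_prime_UTR",
                          "three_prime_UTR"),
                   rep("CDS", cfg$nGenes),
                   ifelse(strand == "+", "three_prime_UTR",
                          "five_prime_UTR"))
    ord <- rep(seq_len(cfg$nGenes), each = 4L)
    parts <- GRanges(chrom[ord],
                     IRanges(as.vector(t(pStart)), as.vector(t(pEnd))),
                     strand = strand[ord])
    mcols(parts)$gene_id <- geneIdv[ord]
    mcols(parts)$feature <- as.vector(t(pFeat))
    catalog <- new("GeneCatalog", genes = genes, parts = parts,
                   chromLengths = stats::setNames(
                       as.numeric(chromLengths), names(chromLengths)))

    ## ---- functional list and regulated sets --------------------------
    nF <- round(cfg$fracFunctional * cfg$nGenes)
    functionalGenes <- sort(sample(geneIdv, nF))
    pathway <- sample(names(cfg$pathwayWeights), nF, replace = TRUE,
                      prob = cfg$pathwayWeights)
    functional <- data.frame(gene_id = functionalGenes,
                             symbol = symbols[match(functionalGenes,
                                                    geneIdv)],
                             pathway = pathway, stringsAsFactors = FALSE)
    nA <- round(cfg$fracTargeted * nF)
    nB <- round(cfg$fracDmGenes * nF)
    sets <- plantRegulationSets(functionalGenes, nA, nB, cfg$rhoDual)

    ## ---- expression profiles -----------------------------------------
    shapes <- .profileShapes(times)
    nT <- length(times)
    pickProfile <- function() {
        sh <- shapes[[sample(length(shapes), 1)]]
        s <- sample(c(-1, 1), 1)
        s * cfg$lfcEffect * stats::runif(1, 0.85, 1.15) * sh
    }
    mirnaProfile <- matrix(0, cfg$nMirnas, nT,
                           dimnames = list(mirnaIdv, times))
    deMirnas <- sort(sample(mirnaIdv, round(cfg$fracDeMirnas *
                                            cfg$nMirnas)))
    for (m in deMirnas) mirnaProfile[m, ] <- pickProfile()

    ## ---- target pairs -------------------------------------------------
    regions <- c("utr5", "cds", "utr3")
    pairRows <- list()
    geneProfile <- matrix(0, cfg$nGenes, nT,
                          dimnames = list(geneIdv, times))
    compStart <- cbind(utr5 = rep(0L, cfg$nGenes), cds = l5,
                       utr3 = l5 + lc)
    compEnd <- cbind(utr5 = l5, cds = l5 + lc, utr3 = glen)
    if (length(sets$mirna) && length(deMirnas)) {
        for (g in sets$mirna) {
            gi <- match(g, geneIdv)
            nPartners <- 1L + stats::rbinom(1, 1, 0.3)
            partners <- sample(deMirnas, min(nPartners, length(deMirnas)))
            for (k in seq_along(partners)) {
                reg <- sample(regions, 1, prob = cfg$regionWeights)
                sgn <- if (stats::runif(1) < cfg$negCorrFrac[reg])
                    "negative" else "positive"
                len <- 21L
                t0 <- compStart[gi, reg] +
                    sample.int(max(1L, compEnd[gi, reg] -
                                   compStart[gi, reg] - len), 1) - 1L
                pairRows[[length(pairRows) + 1L]] <- data.frame(
                    mirna_id = partners[k], gene_id = g,
                    t_start = t0, t_end = t0 + len, region = reg,
                    sign = sgn, stringsAsFactors = FALSE)
                if (k == 1L) {
                    coupl <- if (sgn == "negative") -1 else 1
                    geneProfile[g, ] <- coupl *
                        mirnaProfile[partners[k], ]
                }
            }
        }
    }
    truePairs <- if (length(pairRows)) do.call(rbind, pairRows) else
        data.frame(mirna_id = character(0), gene_id = character(0),
                   t_start = integer(0), t_end = integer(0),
                   region = character(0), sign = character(0),
                   stringsAsFactors = FALSE)

    ## ---- remaining DE genes ------------------------------------------
    others <- setdiff(geneIdv, sets$mirna)
    ownDe <- others[stats::runif(length(others)) < cfg$fracDeGenes]
    for (g in ownDe) geneProfile[g, ] <- pickProfile()

    ## ---- counts -------------------------------------------------------
    drawCounts <- function(profile, base) {
        n <- nrow(profile)
        out <- matrix(0L, n, nrow(sheet),
                      dimnames = list(rownames(profile), sheet$sample_id))
        for (j in seq_len(nrow(sheet))) {
            tcol <- match(sheet$time_h[j], times)
            mu <- base * 2^profile[, tcol]
            out[, j] <- stats::rnbinom(n, mu = mu,
                                       size = 1 / cfg$nbDispersion)
        }
        out
    }
    geneBase <- exp(stats::rnorm(cfg$nGenes, log(300), 0.7))
    mirnaBase <- exp(stats::rnorm(cfg$nMirnas, log(300), 0.7))
    geneCounts <- drawCounts(geneProfile, geneBase)
    mirnaCounts <- drawCounts(mirnaProfile, mirnaBase)

    ## ---- methylation --------------------------------------------------
    targeted <- geneIdv %in% sets$mirna
    lam <- cfg$cpgPerGene * ifelse(targeted, cfg$siteCountDeficit, 1)
    nSites <- stats::rpois(cfg$nGenes, lam)
    inMeth <- geneIdv %in% sets$meth
    nSites[inMeth] <- pmax(1L, nSites[inMeth])
    siteGene <- rep(geneIdv, nSites)
    totalSites <- sum(nSites)
    prom <- promoterRegions(catalog)
    gidx <- match(siteGene, geneIdv)
    lo <- pmin(start(prom)[gidx], startv[gidx])
    hi <- pmax(end(prom)[gidx], endv[gidx])
    sitePos <- lo + floor(stats::runif(totalSites) * (hi - lo + 1))
    # unique positions per chromosome
    key <- paste(chrom[gidx], sitePos)
    while (anyDuplicated(key)) {
        dup <- duplicated(key)
        sitePos[dup] <- lo[dup] + floor(stats::runif(sum(dup)) *
                                        (hi[dup] - lo[dup] + 1))
        key <- paste(chrom[gidx], sitePos)
    }
    muSite <- cfg$bbMu - cfg$deltaTargeted * targeted[gidx]
    p0 <- .rbetaMeanConc(totalSites, pmax(muSite, 0.02),
                         cfg$bbConcentration)
    p0 <- pmin(pmax(p0, 0.02), 0.95)
    isDm <- logical(totalSites)
    firstOfGene <- !duplicated(siteGene)
    isDm[inMeth[gidx] & firstOfGene] <- TRUE
    extra <- inMeth[gidx] & !firstOfGene
    isDm[extra] <- stats::runif(sum(extra)) < cfg$fracDmSites
    dmDir <- sample(c(1, -1), totalSites, replace = TRUE)
    shift <- cfg$dmShift / 100
    outOfRange <- (p0 + dmDir * shift > 0.98) | (p0 + dmDir * shift < 0.02)
    dmDir[outOfRange] <- -dmDir[outOfRange]
    p1 <- pmin(pmax(p0 + dmDir * shift, 0.02), 0.98)

    methTables <- stats::setNames(vector("list", nrow(sheet)),
                                  sheet$sample_id)
    for (j in seq_len(nrow(sheet))) {
        lvl <- ifelse(isDm & sheet$time_h[j] > 0, p1, p0)
        q <- .rbetaMeanConc(totalSites, lvl, cfg$sampleConcentration)
        cov <- stats::rpois(totalSites, cfg$meanCoverage)
        meth <- stats::rbinom(totalSites, cov, q)
        methTables[[j]] <- data.frame(
            chrom = chrom[gidx], pos = sitePos, strand = "+",
            meth_count = meth, unmeth_count = cov - meth,
            stringsAsFactors = FALSE)
    }

    ## ---- prediction files (true pairs + decoys) ----------------------
    predRow <- function(df, tool) {
        n <- nrow(df)
        if (!n) {
            return(data.frame(mirna_id = character(0),
                              gene_id = character(0),
                              t_start = integer(0), t_end = integer(0),
                              energy_kcal_mol = numeric(0),
                              tool = character(0),
                              stringsAsFactors = FALSE))
        }
        data.frame(mirna_id = df$mirna_id, gene_id = df$gene_id,
                   t_start = df$t_start, t_end = df$t_end,
                   energy_kcal_mol = round(stats::runif(n, -35, -20.5), 2),
                   tool = tool, stringsAsFactors = FALSE)
    }
    predsA <- predRow(truePairs, "toolA")
    predsB <- predRow(truePairs, "toolB")
    trueKey <- paste(truePairs$mirna_id, truePairs$gene_id)
    decoyPair <- function(n) {
        out <- data.frame(mirna_id = sample(mirnaIdv, n, replace = TRUE),
                          gene_id = sample(geneIdv, n, replace = TRUE),
                          stringsAsFactors = FALSE)
        keep <- !(paste(out$mirna_id, out$gene_id) %in% trueKey)
        out <- out[keep & !duplicated(paste(out$mirna_id, out$gene_id)), ,
                   drop = FALSE]
        tl <- glen[match(out$gene_id, geneIdv)]
        out$t_start <- floor(stats::runif(nrow(out)) * (tl - 21))
        out$t_end <- out$t_start + 21L
        out
    }
    nDecoy <- max(5L, round(0.25 * nrow(truePairs)))
    singleTool <- decoyPair(nDecoy)
    weakEnergy <- decoyPair(nDecoy)
    shuffled <- decoyPair(nDecoy)
    if (nrow(singleTool)) {
        half <- seq_len(nrow(singleTool)) %% 2 == 0
        predsA <- rbind(predsA, predRow(singleTool[!half, , drop = FALSE],
                                        "toolA"))
        predsB <- rbind(predsB, predRow(singleTool[half, , drop = FALSE],
                                        "toolB"))
    }
    if (nrow(weakEnergy)) {
        predsA <- rbind(predsA, predRow(weakEnergy, "toolA"))
        wk <- predRow(weakEnergy, "toolB")
        wk$energy_kcal_mol <- round(stats::runif(nrow(wk), -19.5, -5), 2)
        predsB <- rbind(predsB, wk)
    }
    if (nrow(shuffled)) {
        # shuffled-gene decoys: swap the gene so the pair exists in one
        # tool only
        predsB <- rbind(predsB, predRow(shuffled, "toolB"))
    }
    rownames(predsA) <- rownames(predsB) <- NULL

    ## ---- truth tables -------------------------------------------------
    contrasts <- defaultContrasts(times)
    deTruth <- function(profile) {
        lapply(contrasts, function(ct) {
            i <- match(ct[1], times)
            j <- match(ct[2], times)
            rownames(profile)[profile[, j] != profile[, i]]
        }) |> stats::setNames(vapply(contrasts, function(ct)
            paste0(ct[1], "vs", ct[2]), character(1)))
    }
    emptyModes <- data.frame(gene_id = character(0), time_h = numeric(0),
                             mode = character(0),
                             stringsAsFactors = FALSE)
    trueModes <- lapply(setdiff(times, 0), function(t) {
        j <- match(t, times)
        cohort <- functionalGenes[
            geneProfile[functionalGenes, j] != 0]
        if (!length(cohort)) return(emptyModes)
        mir <- vapply(cohort, function(g) {
            pr <- truePairs[truePairs$gene_id == g, , drop = FALSE]
            any(mirnaProfile[pr$mirna_id, j] != 0)
        }, logical(1))
        met <- cohort %in% sets$meth
        data.frame(gene_id = cohort, time_h = t,
                   mode = ifelse(mir & met, "dual",
                          ifelse(mir, "mirna_only",
                          ifelse(met, "methylation_only", "none"))),
                   stringsAsFactors = FALSE)
    })
    truth <- list(
        de_genes = deTruth(geneProfile),
        de_mirnas = deTruth(mirnaProfile),
        target_pairs = truePairs,
        dm_sites = data.frame(chrom = chrom[gidx], pos = sitePos,
                              gene_id = siteGene, is_dm = isDm,
                              direction = ifelse(dmDir > 0, "up", "down"),
                              base_level = p0, stress_level = p1,
                              stringsAsFactors = FALSE),
        mirna_genes = sort(sets$mirna),
        meth_genes = sort(sets$meth),
        modes = do.call(rbind, trueModes))

    structure(list(catalog = catalog, sheet = sheet,
                   geneCounts = geneCounts, mirnaCounts = mirnaCounts,
                   predictionsA = predsA, predictionsB = predsB,
                   methTables = methTables, functional = functional,
                   truth = truth, config = cfg, seed = seed),
              class = "SimBundle")
}

#' @export
print.SimBundle <- function(x, ...) {
    cat("SimBundle:", nrow(x$geneCounts), "genes,", nrow(x$mirnaCounts),
        "miRNAs,", nrow(x$sheet), "samples,",
        nrow(x$truth$dm_sites), "CpG sites (seed", x$seed, ")\n")
    cat("  planted:", length(x$truth$mirna_genes), "miRNA-regulated,",
        length(x$truth$meth_genes), "methylation-regulated,",
        length(intersect(x$truth$mirna_genes, x$truth$meth_genes)),
        "dual\n")
    invisible(x)
}

.writeTsv <- function(df, path, schema = TRUE) {
    con <- file(path, "w")
    on.exit(close(con))
    if (schema) writeLines(paste0("# columns: ",
                                  paste(names(df), collapse = ", ")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Write a bundle to a directory as plain-text files
#'
#' Emits the full file tree: GFF3 annotation, count TSVs, sample sheet,
#' the two prediction TSVs, per-sample CpG tables under \code{meth/}, the
#' functional gene list, and all truth tables under \code{truth/}.
#' Byte-identical for identical config and seed.
#'
#' @param bundle a [generateBundle()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the paths written.
#' @export
writeSimBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "meth"), showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    paths <- c(annotation = file.path(dir, "annotation.gff3"),
               gene_counts = file.path(dir, "gene_counts.tsv"),
               mirna_counts = file.path(dir, "mirna_counts.tsv"),
               sample_sheet = file.path(dir, "sample_sheet.tsv"),
               predictions_a = file.path(dir, "predictions_toolA.tsv"),
               predictions_b = file.path(dir, "predictions_toolB.tsv"),
               functional = file.path(dir, "functional_genes.tsv"))
    writeAnnotation(bundle$catalog, paths["annotation"])
    cdf <- function(m) data.frame(entity_id = rownames(m), m,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
    .writeTsv(cdf(bundle$geneCounts), paths["gene_counts"])
    .writeTsv(cdf(bundle$mirnaCounts), paths["mirna_counts"])
    .writeTsv(bundle$sheet, paths["sample_sheet"])
    .writeTsv(bundle$predictionsA, paths["predictions_a"])
    .writeTsv(bundle$predictionsB, paths["predictions_b"])
    .writeTsv(bundle$functional, paths["functional"])
    for (s in names(bundle$methTables)) {
        .writeTsv(bundle$methTables[[s]],
                  file.path(dir, "meth", paste0(s, ".tsv")))
    }
    tr <- bundle$truth
    deDf <- function(lst) do.call(rbind, lapply(names(lst), function(k)
        if (length(lst[[k]])) data.frame(contrast = k,
                                         entity_id = lst[[k]],
                                         stringsAsFactors = FALSE)))
    .writeTsv(deDf(tr$de_genes), file.path(dir, "truth", "de_genes.tsv"))
    .writeTsv(deDf(tr$de_mirnas),
              file.path(dir, "truth", "de_mirnas.tsv"))
    .writeTsv(tr$target_pairs,
              file.path(dir, "truth", "target_pairs.tsv"))
    .writeTsv(tr$dm_sites, file.path(dir, "truth", "dm_sites.tsv"))
    .writeTsv(data.frame(set = c(rep("mirna", length(tr$mirna_genes)),
                                 rep("meth", length(tr$meth_genes))),
                         gene_id = c(tr$mirna_genes, tr$meth_genes),
                         stringsAsFactors = FALSE),
              file.path(dir, "truth", "regulated_sets.tsv"))
    .writeTsv(tr$modes, file.path(dir, "truth", "modes.tsv"))
    invisible(paths)
}

#' Recovery of planted truth by the pipeline
#'
#' Compares pipeline outputs against a bundle's truth tables:
#' sensitivity/specificity of differential-expression calls, target-pair
#' recovery against the decoy-laden candidate space, differential-site
#' recovery, and the regulation-mode confusion matrix.
#'
#' @param bundle the [generateBundle()] result the pipeline ran on.
#' @param result the [runIntegration()] result.
#' @return list with \code{de_genes} (per-contrast data.frame),
#'   \code{target_pairs} (sensitivity/specificity), \code{dm_sites},
#'   \code{mode_confusion} (table) and \code{mode_agreement} (fraction of
#'   matching mode calls on the shared gene-time cohort).
#' @export
truthRecoveryReport <- function(bundle, result) {
    senspec <- function(called, truthSet, universe) {
        truthSet <- intersect(truthSet, universe)
        called <- intersect(called, universe)
        neg <- setdiff(universe, truthSet)
        data.frame(
            n_truth = length(truthSet), n_called = length(called),
            sensitivity = if (length(truthSet))
                length(intersect(called, truthSet)) / length(truthSet)
                else NA_real_,
            specificity = if (length(neg))
                1 - length(setdiff(called, truthSet)) / length(neg)
                else NA_real_)
    }
    universeG <- rownames(bundle$geneCounts)
    deRows <- do.call(rbind, lapply(names(bundle$truth$de_genes),
        function(k) {
            called <- result$de_genes_by_contrast[[k]]
            if (is.null(called)) stop("pipeline result lacks contrast ", k)
            cbind(contrast = k,
                  senspec(called, bundle$truth$de_genes[[k]], universeG))
        }))
    predKeys <- unique(c(paste(bundle$predictionsA$mirna_id,
                               bundle$predictionsA$gene_id),
                         paste(bundle$predictionsB$mirna_id,
                               bundle$predictionsB$gene_id)))
    trueKeys <- unique(paste(bundle$truth$target_pairs$mirna_id,
                             bundle$truth$target_pairs$gene_id))
    calledKeys <- unique(paste(result$pairs$mirna_id,
                               result$pairs$gene_id))
    pairRow <- senspec(calledKeys, trueKeys, predKeys)
    dmTruth <- bundle$truth$dm_sites
    dmKeys <- paste(dmTruth$chrom, dmTruth$pos)[dmTruth$is_dm]
    allKeys <- paste(dmTruth$chrom, dmTruth$pos)
    calledDm <- unique(unlist(lapply(result$diff_sites, function(d)
        paste(d$chrom, d$pos))))
    dmRow <- senspec(calledDm, dmKeys, allKeys)
    tm <- bundle$truth$modes
    cm <- result$regulation_calls
    key <- function(df) paste(df$gene_id, df$time_h)
    shared <- intersect(key(tm), key(cm))
    conf <- table(truth = tm$mode[match(shared, key(tm))],
                  called = cm$mode[match(shared, key(cm))])
    agree <- if (length(shared))
        mean(tm$mode[match(shared, key(tm))] ==
             cm$mode[match(shared, key(cm))]) else NA_real_
    list(de_genes = deRows, target_pairs = pairRow, dm_sites = dmRow,
         mode_confusion = conf, mode_agreement = agree)
}
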