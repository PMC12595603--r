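#' Classify regulation mode of functional genes at one time point
#'
#' For each functional gene differentially expressed at the sampling time,
#' miRNA evidence is membership on the gene side of the active target
#' pairs, methylation evidence is membership among the DMSGs of the
#' matching 0 h-vs-t contrast, and the mode follows the 2x2 evidence
#' table: \code{mirna_only}, \code{methylation_only}, \code{dual} or
#' \code{none}. With \code{cohort = "functional"} the classification runs
#' over all functional genes instead (genes without expression change
#' included).
#'
#' @param time_h the sampling time.
#' @param degs differential genes at the time (character vector or
#'   DifferentialSet).
#' @param activePairs active target pairs at the time (see
#'   [pairsActiveAt()]).
#' @param dmsgs DMSG table for the matching contrast (see
#'   [buildDmsgs()]).
#' @param functionalGenes character vector of functional gene ids.
#' @param cohort \code{"de"} (default: functional genes differential at t)
#'   or \code{"functional"} (all functional genes).
#' @return data.frame with columns gene_id, time_h, mode, n_pairs,
#'   n_sites.
#' @export
classifyRegulation <- function(time_h, degs, activePairs, dmsgs,
                               functionalGenes,
                               cohort = c("de", "functional")) {
    cohort <- match.arg(cohort)
    ids <- function(x) if (inherits(x, "DifferentialSet")) x$entity_ids else x
    genes <- if (cohort == "de") intersect(functionalGenes, ids(degs)) else
        functionalGenes
    nPairs <- vapply(genes, function(g)
        sum(activePairs$gene_id == g), integer(1))
    nSites <- vapply(genes, function(g)
        sum(dmsgs$gene_id == g), integer(1))
    mode <- ifelse(nPairs > 0 & nSites > 0, "dual",
            ifelse(nPairs > 0, "mirna_only",
            ifelse(nSites > 0, "methylation_only", "none")))
    data.frame(gene_id = genes, time_h = time_h, mode = mode,
               n_pairs = nPairs, n_sites = nSites,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Regulation-mode proportions at one time point
#'
#' Fractions of miRNA-only, methylation-only and dually regulated genes
#' among the genes carrying at least one kind of evidence (the pie-chart
#' proportions), plus the count of evidence-free genes.
#'
#' @param calls data.frame from [classifyRegulation()] (one time point).
#' @return list with \code{proportions} (named, sums to 1 when any
#'   evidence exists), \code{counts}, and \code{n_none}.
#' @export
modeProportions <- function(calls) {
    modes <- c("mirna_only", "methylation_only", "dual")
    counts <- stats::setNames(vapply(modes, function(m)
        sum(calls$mode == m), numeric(1)), modes)
    total <- sum(counts)
    list(proportions = if (total > 0) counts / total else counts * NA_real_,
         counts = counts,
         n_none = sum(calls$mode == "none"))
}

#' Permutation test for non-random dual regulation
#'
#' Draws, at each iteration, two independent uniform without-replacement
#' gene sets of the observed sizes from the universe and records their
#' overlap; the empirical p-value for the observed overlap uses the
#' add-one convention \eqn{(1 + \#\{null \ge obs\})/(iterations + 1)},
#' which never returns 0. Redrawing both sets each iteration is
#' distributionally equivalent to fixing one set, and the null overlap is
#' hypergeometric.
#'
#' @param universe character vector of gene ids forming the sampling
#'   frame (typically the functional gene list).
#' @param setMirna,setMeth subsets of \code{universe}: the miRNA-regulated
#'   and methylation-regulated genes.
#' @param iterations Monte-Carlo iterations (default 1000).
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @return a [PermutationResult-class].
#' @export
dualRegulationPermutation <- function(universe, setMirna, setMeth,
                                      iterations = 1000, seed = NULL) {
    universe <- unique(universe)
    N <- length(universe)
    if (!all(setMirna %in% universe) || !all(setMeth %in% universe))
        stop("regulated sets must be subsets of the universe")
    nA <- length(unique(setMirna))
    nB <- length(unique(setMeth))
    if (nA > N || nB > N) stop("set larger than universe")
    kObs <- length(intersect(setMirna, setMeth))

    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
        })
        set.seed(seed)
    }
    nulls <- integer(iterations)
    member <- logical(N)
    for (i in seq_len(iterations)) {
        a <- sample.int(N, nA)
        b <- sample.int(N, nB)
        member[a] <- TRUE
        nulls[i] <- sum(member[b])
        member[a] <- FALSE
    }
    p <- (1 + sum(nulls >= kObs)) / (iterations + 1)
    new("PermutationResult",
        universeSize = as.integer(N), nMirna = as.integer(nA),
        nMeth = as.integer(nB), observedOverlap = as.integer(kObs),
        iterations = as.integer(iterations), nullOverlaps = nulls,
        pEmpirical = p,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Structural complementarity of miRNA targeting and methylation
#'
#' Compares, per sampling time, the gene-level methylation of
#' miRNA-targeted versus non-targeted genes (two-sided rank-sum test with
#' significance stars) and, once across genes, their CpG site counts --
#' the analysis behind the observation that targeted genes carry lower
#' methylation and fewer methylation-capable sites.
#'
#' @param targetedGenes,otherGenes character vectors of gene ids.
#' @param levels genes x times numeric matrix of gene methylation levels
#'   (rows named by gene id; NA rows are excluded and counted).
#' @param siteCounts named numeric vector of per-gene CpG site counts
#'   (optional).
#' @return list with \code{levels}: data.frame(time, n_targeted,
#'   n_other, mean_targeted, sd_targeted, mean_other, sd_other, p, stars),
#'   \code{site_counts}: one-row data.frame or NULL, and
#'   \code{n_missing}: genes dropped for having no level.
#' @export
structuralComplementarity <- function(targetedGenes, otherGenes, levels,
                                      siteCounts = NULL) {
    rows <- list()
    nMissing <- 0L
    for (tcol in colnames(levels)) {
        lt <- levels[intersect(targetedGenes, rownames(levels)), tcol]
        lo <- levels[intersect(otherGenes, rownames(levels)), tcol]
        nMissing <- nMissing + sum(is.na(lt)) + sum(is.na(lo))
        lt <- lt[!is.na(lt)]
        lo <- lo[!is.na(lo)]
        if (!length(lt) || !length(lo)) {
            warning("skipping time ", tcol, ": empty comparison group")
            next
        }
        wt <- wilcoxonRankSum(lt, lo)
        rows[[tcol]] <- data.frame(
            time = tcol, n_targeted = length(lt), n_other = length(lo),
            mean_targeted = mean(lt), sd_targeted = stats::sd(lt),
            mean_other = mean(lo), sd_other = stats::sd(lo),
            p = wt$p_value, stars = significanceStars(wt$p_value),
            stringsAsFactors = FALSE)
    }
    lev <- do.call(rbind, rows)
    if (!is.null(lev)) rownames(lev) <- NULL
    out <- list(levels = lev, site_counts = NULL, n_missing = nMissing)
    if (!is.null(siteCounts)) {
        st <- siteCounts[intersect(targetedGenes, names(siteCounts))]
        so <- siteCounts[intersect(otherGenes, names(siteCounts))]
        if (length(st) && length(so)) {
            wt <- wilcoxonRankSum(st, so)
            out$site_counts <- data.frame(
                n_targeted = length(st), n_other = length(so),
                mean_targeted = mean(st), sd_targeted = stats::sd(st),
                mean_other = mean(so), sd_other = stats::sd(so),
                p = wt$p_value, stars = significanceStars(wt$p_value),
                stringsAsFactors = FALSE)
        }
    }
    out
}

#' |log2FC| comparison across regulation modes
#'
#' Two-sided rank-sum tests of |log2 fold change| between the miRNA-only
#' and dual groups and between the methylation-only and dual groups --
#' the check on whether dual regulation amplifies expression changes.
#'
#' @param calls data.frame from [classifyRegulation()] (one time point).
#' @param lfc named numeric vector of the genes' log2 fold changes at the
#'   same contrast.
#' @return data.frame with one row per comparison: groups, sizes, p
#'   (NA when a group is empty, reported as not computable).
#' @export
lfcGroupComparison <- function(calls, lfc) {
    grp <- function(mode) {
        g <- calls$gene_id[calls$mode == mode]
        abs(lfc[intersect(g, names(lfc))])
    }
    mo <- grp("mirna_only")
    me <- grp("methylation_only")
    du <- grp("dual")
    cmp <- function(a, b, label) {
        data.frame(comparison = label, n1 = length(a), n2 = length(b),
                   p = if (length(a) && length(b))
                       wilcoxonRankSum(a, b)$p_value else NA_real_,
                   stringsAsFactors = FALSE)
    }
    rbind(cmp(mo, du, "mirna_only_vs_dual"),
          cmp(me, du, "methylation_only_vs_dual"))
}

#' Cross-layer regulation of epigenetic-machinery genes
#'
#' Scans the target pairs and DMSG table for a watchlist of genes from the
#' two machineries themselves -- methyl-CpG readers and miRNA biogenesis
#' factors -- reporting miRNA-target hits (region and correlation sign)
#' and methylation hits (site count and directions).
#'
#' @param pairs region-assigned, correlation-attached target pairs with a
#'   \code{symbol} column (or gene ids matching the watchlist).
#' @param dmsgs DMSG table from [buildDmsgs()].
#' @param watchlist gene symbols to scan for (default MBD2, DGCR8, DNMT,
#'   Dicer, Drosha).
#' @return data.frame with columns symbol, layer (mirna/methylation),
#'   detail columns mirna_id, region, sign, site_count, directions.
#' @export
mutualRegulationReport <- function(pairs, dmsgs,
                                   watchlist = c("MBD2", "DGCR8", "DNMT",
                                                 "Dicer", "Drosha")) {
    rows <- list()
    psym <- if (!is.null(pairs$symbol)) pairs$symbol else pairs$gene_id
    for (w in watchlist) {
        sel <- which(toupper(psym) == toupper(w))
        for (i in sel) {
            rows[[length(rows) + 1L]] <- data.frame(
                symbol = w, layer = "mirna",
                mirna_id = pairs$mirna_id[i],
                region = if (!is.null(pairs$region)) pairs$region[i] else
                    NA_character_,
                sign = if (!is.null(pairs$sign)) pairs$sign[i] else
                    NA_character_,
                site_count = NA_integer_, directions = NA_character_,
                stringsAsFactors = FALSE)
        }
        dsel <- which(toupper(dmsgs$symbol) == toupper(w))
        if (length(dsel)) {
            rows[[length(rows) + 1L]] <- data.frame(
                symbol = w, layer = "methylation",
                mirna_id = NA_character_, region = NA_character_,
                sign = NA_character_,
                site_count = length(dsel),
                directions = paste(sort(unique(dmsgs$direction[dsel])),
                                   collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) {
        return(data.frame(symbol = character(0), layer = character(0),
                          mirna_id = character(0), region = character(0),
                          sign = character(0), site_count = integer(0),
                          directions = character(0),
                          stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
}

#' One-sided hypergeometric enrichment for a user-supplied term map
#'
#' Hook for functional-term enrichment of dually regulated genes against a
#' caller-provided gene-to-term map (no bundled databases): per term, a
#' one-sided hypergeometric tail test of overlap with the gene set,
#' Benjamini-Hochberg adjusted.
#'
#' @param genes gene set of interest (e.g. dually regulated genes).
#' @param universe background gene ids.
#' @param termMap data.frame with columns gene_id and term.
#' @return data.frame with columns term, n_term, n_overlap, p, p_adj.
#' @export
termEnrichment <- function(genes, universe, termMap) {
    genes <- intersect(genes, universe)
    termMap <- termMap[termMap$gene_id %in% universe, , drop = FALSE]
    terms <- unique(termMap$term)
    if (!length(terms)) {
        return(data.frame(term = character(0), n_term = integer(0),
                          n_overlap = integer(0), p = numeric(0),
                          p_adj = numeric(0), stringsAsFactors = FALSE))
    }
    N <- length(universe)
    res <- lapply(terms, function(tm) {
        tg <- unique(termMap$gene_id[termMap$term == tm])
        k <- length(intersect(tg, genes))
        p <- stats::phyper(k - 1, length(tg), N - length(tg),
                           length(genes), lower.tail = FALSE)
        data.frame(term = tm, n_term = length(tg), n_overlap = k, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adj <- benjaminiHochberg(out$p)
    out
}
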