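#' Load per-sample CpG methylation call tables
#'
#' Each per-sample TSV has columns chrom, pos (1-based), strand,
#' meth_count, unmeth_count. Sites are aligned across samples on
#' (chrom, pos, strand) and filtered to those with coverage
#' (meth + unmeth) of at least \code{minCoverage} in every sample, so that
#' every retained site is usable in any contrast. Symmetric CpG pairs
#' (+ strand position p, - strand position p+1) can optionally be merged by
#' summing counts onto the + strand position.
#'
#' @param paths named character vector of file paths; names are sample ids
#'   and must match the sheet.
#' @param sheet sample sheet (see [readSampleSheet()]).
#' @param minCoverage minimum per-sample coverage (default 10).
#' @param mergeStrands merge symmetric CpG pairs (default FALSE).
#' @return a \code{SummarizedExperiment} with assays \code{meth} and
#'   \code{unmeth}, width-1 \code{rowRanges} and the sheet as
#'   \code{colData}.
#' @export
loadMethylationCalls <- function(paths, sheet, minCoverage = 10,
                                 mergeStrands = FALSE) {
    stopifnot(!is.null(names(paths)))
    if (!setequal(names(paths), sheet$sample_id))
        stop("file names and sample sheet disagree on sample ids")
    paths <- paths[sheet$sample_id]
    tabs <- lapply(paths, function(p)
        utils::read.table(p, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
    for (s in names(tabs)) {
        tb <- tabs[[s]]
        need <- c("chrom", "pos", "strand", "meth_count", "unmeth_count")
        miss <- setdiff(need, names(tb))
        if (length(miss)) stop("sample ", s, " missing column(s): ",
                               paste(miss, collapse = ", "))
        if (anyDuplicated(paste(tb$chrom, tb$pos)))
            stop("conflicting strand at duplicated coordinate in sample ",
                 s)
        if (any(tb$meth_count < 0 | tb$unmeth_count < 0))
            stop("negative counts in sample ", s)
    }
    methylationCallsFromTables(tabs, sheet, minCoverage = minCoverage,
                               mergeStrands = mergeStrands)
}

#' @rdname loadMethylationCalls
#' @param tables named list of per-sample data.frames with the same
#'   columns as the TSVs.
#' @export
methylationCallsFromTables <- function(tables, sheet, minCoverage = 10,
                                       mergeStrands = FALSE) {
    tables <- tables[sheet$sample_id]
    key <- function(tb) paste(tb$chrom, tb$pos, tb$strand, sep = "\r")
    keys <- Reduce(union, lapply(tables, key))
    asMat <- function(col) {
        m <- vapply(tables, function(tb) {
            v <- rep(0, length(keys))
            v[match(key(tb), keys)] <- tb[[col]]
            v
        }, numeric(length(keys)))
        # vapply drops to a vector when only one site remains
        if (is.null(dim(m)))
            m <- matrix(m, nrow = length(keys),
                        dimnames = list(NULL, names(tables)))
        m
    }
    meth <- asMat("meth_count")
    unmeth <- asMat("unmeth_count")
    kk <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    chrom <- kk[, 1]
    pos <- as.integer(kk[, 2])
    strand <- kk[, 3]

    if (mergeStrands) {
        minusKey <- paste(chrom, pos - 1L, "+", sep = "\r")
        isMinus <- strand == "-"
        partner <- match(minusKey, keys)
        mergeTo <- ifelse(isMinus & !is.na(partner), partner,
                          seq_along(keys))
        keep <- !(isMinus & !is.na(partner))
        methM <- rowsum(meth, mergeTo)
        unmethM <- rowsum(unmeth, mergeTo)
        sel <- as.integer(rownames(methM))
        meth <- methM
        unmeth <- unmethM
        chrom <- chrom[sel]
        pos <- pos[sel]
        strand <- ifelse(keep[sel], strand[sel], "+")
        strand[strand == "-" & !keep[sel]] <- "+"
    }

    cov <- meth + unmeth
    ok <- apply(cov >= minCoverage, 1, all)
    gr <- GRanges(chrom[ok], IRanges(pos[ok], pos[ok]),
                  strand = strand[ok])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth[ok, , drop = FALSE],
                      unmeth = unmeth[ok, , drop = FALSE]),
        rowRanges = gr,
        colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample_id))
    ord <- order(as.character(seqnames(gr)), start(gr))
    se[ord, ]
}

#' Differential methylation between two sample groups
#'
#' Per site, counts are pooled within each group and compared with a
#' two-sided Fisher exact test; the methylation difference is the
#' percentage-point difference of pooled rates (test minus reference);
#' q-values are Benjamini-Hochberg over all tested sites. A site is called
#' differential when strictly |meth_diff| >= \code{diffMin} points and
#' q < \code{qMax}. Defaults (25 points, q < 0.01, together with the
#' loader's coverage >= 10) are the conventional cutoffs of site-level
#' WGBS differential analysis and are configurable.
#'
#' @param calls SummarizedExperiment from [loadMethylationCalls()].
#' @param groupA,groupB sample ids of the reference and test groups.
#' @param diffMin minimum |difference| in percentage points (default 25).
#' @param qMax q-value cutoff, exclusive (default 0.01).
#' @param returnAll return all tested sites with a \code{significant}
#'   column instead of only the differential ones (default FALSE).
#' @return data.frame with columns chrom, pos, strand, meth_diff,
#'   p_value, q_value, direction (and \code{significant} when
#'   \code{returnAll}).
#' @export
diffMethylation <- function(calls, groupA, groupB, diffMin = 25.0,
                            qMax = 0.01, returnAll = FALSE) {
    if (!length(groupA) || !length(groupB))
        stop("both groups need >= 1 sample")
    m <- SummarizedExperiment::assay(calls, "meth")
    u <- SummarizedExperiment::assay(calls, "unmeth")
    if (!all(c(groupA, groupB) %in% colnames(m)))
        stop("unknown sample id in contrast groups")
    mA <- rowSums(m[, groupA, drop = FALSE])
    uA <- rowSums(u[, groupA, drop = FALSE])
    mB <- rowSums(m[, groupB, drop = FALSE])
    uB <- rowSums(u[, groupB, drop = FALSE])
    rateA <- mA / (mA + uA)
    rateB <- mB / (mB + uB)
    p <- vapply(seq_along(mA), function(i)
        stats::fisher.test(matrix(c(mA[i], uA[i], mB[i], uB[i]), 2))$p.value,
        numeric(1))
    p <- pmin(p, 1)  # guard against rounding just above 1
    q <- benjaminiHochberg(p)
    gr <- SummarizedExperiment::rowRanges(calls)
    diff <- 100 * (rateB - rateA)
    out <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                      strand = as.character(strand(gr)),
                      meth_diff = diff, p_value = p, q_value = q,
                      direction = ifelse(diff > 0, "up", "down"),
                      stringsAsFactors = FALSE)
    out$significant <- abs(out$meth_diff) >= diffMin & out$q_value < qMax
    if (!returnAll) {
        out <- out[out$significant, setdiff(names(out), "significant"),
                   drop = FALSE]
        rownames(out) <- NULL
    }
    out
}

#' Build methylation-related stress-responsive gene records
#'
#' A gene containing at least one differentially methylated site within its
#' gene body or promoter is a DNA methylation-related stress-responsive
#' gene (DMSG); one record is emitted per (gene, site), with the site's
#' promoter/gene-body location, difference direction and, when profiles
#' are supplied downstream, the methylation-expression correlation sign.
#' A site inside the promoter of one gene and the body of an overlapping
#' gene yields one record for each gene.
#'
#' @param diffSites data.frame from [diffMethylation()].
#' @param catalog a [GeneCatalog-class].
#' @param functionalList optional data.frame with columns gene_id and
#'   pathway (and optionally symbol); when supplied only functional genes
#'   are kept and the pathway label is attached.
#' @param upstream promoter size (default 2000).
#' @param strandAware see [promoterRegions()].
#' @return data.frame with columns gene_id, symbol, chrom, pos, location,
#'   meth_diff, direction and (when available) function_label.
#' @export
buildDmsgs <- function(diffSites, catalog, functionalList = NULL,
                       upstream = 2000, strandAware = TRUE) {
    if (!nrow(diffSites)) {
        return(data.frame(gene_id = character(0), symbol = character(0),
                          chrom = character(0), pos = integer(0),
                          location = character(0), meth_diff = numeric(0),
                          direction = character(0),
                          function_label = character(0),
                          stringsAsFactors = FALSE))
    }
    ov <- siteGeneOverlaps(catalog, diffSites[, c("chrom", "pos")],
                           upstream = upstream, strandAware = strandAware)
    g <- geneRanges(catalog)
    out <- data.frame(
        gene_id = ov$gene_id,
        symbol = mcols(g)$symbol[match(ov$gene_id, names(g))],
        chrom = ov$chrom, pos = ov$pos, location = ov$location,
        meth_diff = diffSites$meth_diff[ov$site_index],
        direction = diffSites$direction[ov$site_index],
        stringsAsFactors = FALSE)
    if (!is.null(functionalList)) {
        keep <- out$gene_id %in% functionalList$gene_id
        out <- out[keep, , drop = FALSE]
        out$function_label <- functionalList$pathway[
            match(out$gene_id, functionalList$gene_id)]
    }
    rownames(out) <- NULL
    out
}

#' Per-time pooled methylation level of a site set
#'
#' @param calls SummarizedExperiment from [loadMethylationCalls()].
#' @param siteIdx row indices of the sites to pool.
#' @return numeric vector over the design's time points: pooled
#'   meth/(meth+unmeth) over the selected sites and each time's samples.
#' @export
siteMethylationProfile <- function(calls, siteIdx) {
    sheet <- as.data.frame(SummarizedExperiment::colData(calls))
    m <- SummarizedExperiment::assay(calls, "meth")
    u <- SummarizedExperiment::assay(calls, "unmeth")
    times <- sort(unique(sheet$time_h))
    vapply(times, function(t) {
        sel <- sheet$sample_id[sheet$time_h == t]
        sum(m[siteIdx, sel]) / sum(m[siteIdx, sel] + u[siteIdx, sel])
    }, numeric(1)) |> stats::setNames(as.character(times))
}

#' Methylation-expression correlation sign for one gene/site profile
#'
#' Sign of the Pearson correlation between a per-time methylation-level
#' profile and the gene's per-time mean expression profile.
#'
#' @param methProfile numeric per-time methylation levels (n >= 3).
#' @param exprProfile numeric per-time expression means, same times.
#' @return \code{"positive"}, \code{"negative"} or \code{"zero"}.
#' @export
methylationExpressionDirection <- function(methProfile, exprProfile) {
    pearsonCorrelation(methProfile, exprProfile)$sign
}

#' Gene-level methylation summaries
#'
#' The gene-level methylation level is the unweighted mean over the gene's
#' covered CpG sites (promoter plus gene body) of the pooled
#' meth/(meth+unmeth) rate across the selected samples; genes without a
#' covered site get \code{NA} and are excluded from group comparisons.
#'
#' @param calls SummarizedExperiment from [loadMethylationCalls()].
#' @param catalog a [GeneCatalog-class].
#' @param samples sample ids to pool (default all).
#' @param geneIds genes to report (default all in the catalog).
#' @param upstream,strandAware promoter definition, see
#'   [promoterRegions()].
#' @return named numeric vector of levels in [0, 1] (NA when uncovered).
#' @export
geneMethylationLevels <- function(calls, catalog,
                                  samples = colnames(calls),
                                  geneIds = NULL, upstream = 2000,
                                  strandAware = TRUE) {
    if (is.null(geneIds)) geneIds <- geneIds(catalog)
    gr <- SummarizedExperiment::rowRanges(calls)
    ov <- siteGeneOverlaps(catalog,
                           data.frame(chrom = as.character(seqnames(gr)),
                                      pos = start(gr)),
                           upstream = upstream, strandAware = strandAware)
    m <- SummarizedExperiment::assay(calls, "meth")[, samples, drop = FALSE]
    u <- SummarizedExperiment::assay(calls, "unmeth")[, samples,
                                                      drop = FALSE]
    rate <- rowSums(m) / (rowSums(m) + rowSums(u))
    lv <- tapply(rate[ov$site_index], ov$gene_id, mean)
    out <- stats::setNames(rep(NA_real_, length(geneIds)), geneIds)
    hit <- intersect(names(lv), geneIds)
    out[hit] <- lv[hit]
    out
}

#' Per-gene counts of (covered) CpG sites
#'
#' @inheritParams geneMethylationLevels
#' @return named integer vector of site counts (0 for genes without
#'   covered sites).
#' @export
geneSiteCounts <- function(calls, catalog, geneIds = NULL, upstream = 2000,
                           strandAware = TRUE) {
    if (is.null(geneIds)) geneIds <- geneIds(catalog)
    gr <- SummarizedExperiment::rowRanges(calls)
    ov <- siteGeneOverlaps(catalog,
                           data.frame(chrom = as.character(seqnames(gr)),
                                      pos = start(gr)),
                           upstream = upstream, strandAware = strandAware)
    cnt <- table(ov$gene_id)
    out <- stats::setNames(rep(0L, length(geneIds)), geneIds)
    hit <- intersect(names(cnt), geneIds)
    out[hit] <- as.integer(cnt[hit])
    out
}
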