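#' Read a miRNA target-prediction table
#'
#' Canonical prediction dialect shared by both tools: one row per predicted
#' binding site with transcript-coordinate interval (0-based half-open) and
#' duplex energy in kcal/mol (negative = stable duplex). Native report
#' formats of the upstream prediction tools are out of scope; convert them
#' to this dialect (columns below) before loading.
#'
#' @param path TSV with columns mirna_id, gene_id, t_start, t_end,
#'   energy_kcal_mol, tool.
#' @return data.frame of predictions.
#' @export
readPredictions <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("mirna_id", "gene_id", "t_start", "t_end", "energy_kcal_mol",
              "tool")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("prediction table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (any(!is.finite(df$energy_kcal_mol))) stop("non-finite energy")
    if (any(df$t_start >= df$t_end)) stop("empty binding interval")
    df
}

#' Intersect two prediction sources under an energy threshold
#'
#' A (miRNA, gene) pair is a final target pair when it is predicted by both
#' sources and passes the duplex-energy threshold. Overlap is at the
#' (miRNA, gene) level -- the two tools report binding coordinates in
#' different frames, so coordinate agreement is not required. With
#' \code{mode = "per_source"} (default, the stricter reading) the best
#' energy of each source must pass; with \code{mode = "best"} only the
#' overall best energy must. The reported binding interval and energy come
#' from the source with the lower (more negative) energy.
#'
#' @param predsA,predsB prediction data.frames (see [readPredictions()]).
#' @param energyMax keep pairs with energy <= this, kcal/mol (default -20).
#' @param mode \code{"per_source"} or \code{"best"}.
#' @return data.frame with columns mirna_id, gene_id, t_start, t_end,
#'   energy_best, source_best; empty when nothing passes.
#' @export
intersectPredictions <- function(predsA, predsB, energyMax = -20.0,
                                 mode = c("per_source", "best")) {
    mode <- match.arg(mode)
    best <- function(df) {
        key <- paste(df$mirna_id, df$gene_id, sep = "\r")
        i <- tapply(seq_len(nrow(df)), key, function(ii)
            ii[which.min(df$energy_kcal_mol[ii])])
        df <- df[unlist(i), , drop = FALSE]
        df$key <- paste(df$mirna_id, df$gene_id, sep = "\r")
        df
    }
    a <- best(predsA)
    b <- best(predsB)
    shared <- intersect(a$key, b$key)
    if (!length(shared)) {
        return(data.frame(mirna_id = character(0), gene_id = character(0),
                          t_start = numeric(0), t_end = numeric(0),
                          energy_best = numeric(0),
                          source_best = character(0),
                          stringsAsFactors = FALSE))
    }
    a <- a[match(shared, a$key), ]
    b <- b[match(shared, b$key), ]
    pass <- if (mode == "per_source") {
        a$energy_kcal_mol <= energyMax & b$energy_kcal_mol <= energyMax
    } else {
        pmin(a$energy_kcal_mol, b$energy_kcal_mol) <= energyMax
    }
    fromA <- a$energy_kcal_mol <= b$energy_kcal_mol
    out <- data.frame(
        mirna_id = a$mirna_id, gene_id = a$gene_id,
        t_start = ifelse(fromA, a$t_start, b$t_start),
        t_end = ifelse(fromA, a$t_end, b$t_end),
        energy_best = pmin(a$energy_kcal_mol, b$energy_kcal_mol),
        source_best = ifelse(fromA, a$tool, b$tool),
        stringsAsFactors = FALSE)[pass, , drop = FALSE]
    out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Label target pairs with their transcript compartment
#'
#' @param pairs target-pair data.frame with t_start/t_end (0-based
#'   half-open transcript coordinates).
#' @param catalog a [GeneCatalog-class].
#' @return \code{pairs} with an added \code{region} column
#'   (utr5/cds/utr3).
#' @export
assignPairRegions <- function(pairs, catalog) {
    pairs$region <- vapply(seq_len(nrow(pairs)), function(i)
        assignBindingRegion(catalog, pairs$gene_id[i], pairs$t_start[i],
                            pairs$t_end[i]), character(1))
    pairs
}

#' Per-time-point mean expression profiles
#'
#' Mean of median-of-ratios-normalised counts over the replicates of each
#' sampling time, the profile on which miRNA-target and
#' methylation-expression correlations are computed.
#'
#' @param counts entities x samples matrix.
#' @param sheet sample sheet.
#' @param normalize apply size-factor normalisation first (default TRUE).
#' @return matrix entities x time points (columns ordered by time).
#' @export
timeProfiles <- function(counts, sheet, normalize = TRUE) {
    m <- if (normalize) sweep(counts, 2, sizeFactors(counts), "/") else
        counts
    times <- sort(unique(sheet$time_h))
    prof <- vapply(times, function(t) {
        idx <- match(sheet$sample_id[sheet$time_h == t], colnames(m))
        rowMeans(m[, idx, drop = FALSE])
    }, numeric(nrow(m)))
    colnames(prof) <- as.character(times)
    prof
}

#' Attach the miRNA-target expression correlation to each pair
#'
#' Pearson correlation between the miRNA and gene per-time mean profiles
#' over the full design (n = 6 time points including 0 h).
#'
#' @param pairs target-pair data.frame.
#' @param mirnaProfiles,geneProfiles matrices from [timeProfiles()], rows
#'   named by entity id, identical column (time) order.
#' @return \code{pairs} with added columns \code{r}, \code{p},
#'   \code{sign}.
#' @export
attachCorrelation <- function(pairs, mirnaProfiles, geneProfiles) {
    stopifnot(identical(colnames(mirnaProfiles), colnames(geneProfiles)))
    missM <- setdiff(unique(pairs$mirna_id), rownames(mirnaProfiles))
    if (length(missM)) stop("no expression profile for miRNA(s): ",
                            paste(missM, collapse = ", "))
    missG <- setdiff(unique(pairs$gene_id), rownames(geneProfiles))
    if (length(missG)) stop("no expression profile for gene(s): ",
                            paste(missG, collapse = ", "))
    res <- lapply(seq_len(nrow(pairs)), function(i)
        pearsonCorrelation(mirnaProfiles[pairs$mirna_id[i], ],
                           geneProfiles[pairs$gene_id[i], ]))
    pairs$r <- vapply(res, `[[`, numeric(1), "r")
    pairs$p <- vapply(res, `[[`, numeric(1), "p_value")
    pairs$sign <- vapply(res, `[[`, character(1), "sign")
    pairs
}

#' Binding-region distribution and per-region correlation fractions
#'
#' @param pairs region-assigned (and optionally correlation-attached)
#'   target pairs.
#' @return list with \code{counts} and \code{proportions} over
#'   utr5/cds/utr3 (proportions sum to 1 when pairs exist) and, when a
#'   \code{sign} column is present, \code{sign_fractions}: per region the
#'   positive/negative fractions among non-zero signs.
#' @export
bindingRegionDistribution <- function(pairs) {
    regions <- c("utr5", "cds", "utr3")
    counts <- stats::setNames(vapply(regions, function(r)
        sum(pairs$region == r), numeric(1)), regions)
    total <- sum(counts)
    props <- if (total > 0) counts / total else counts * NA_real_
    out <- list(counts = counts, proportions = props)
    if (!is.null(pairs$sign)) {
        out$sign_fractions <- t(vapply(regions, function(r) {
            s <- pairs$sign[pairs$region == r & pairs$sign != "zero"]
            n <- length(s)
            c(positive = if (n) mean(s == "positive") else NA_real_,
              negative = if (n) mean(s == "negative") else NA_real_)
        }, numeric(2)))
    }
    out
}

#' Target pairs active at a sampling time
#'
#' A pair is active at time t when both its miRNA and its target gene are
#' differentially expressed in the 0 h-vs-t contrast (the target then being
#' a differentially expressed target gene).
#'
#' @param pairs target-pair data.frame.
#' @param demirnas character vector (or DifferentialSet) of differential
#'   miRNAs at the time.
#' @param degs character vector (or DifferentialSet) of differential genes
#'   at the time.
#' @return the active subset of \code{pairs}.
#' @export
pairsActiveAt <- function(pairs, demirnas, degs) {
    ids <- function(x) if (inherits(x, "DifferentialSet")) x$entity_ids else x
    out <- pairs[pairs$mirna_id %in% ids(demirnas) &
                 pairs$gene_id %in% ids(degs), , drop = FALSE]
    rownames(out) <- NULL
    out
}
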