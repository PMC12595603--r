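#' Read a sample sheet
#'
#' The sheet describes the repeated-stress design: sampling time in hours
#' (0, 24, 48, 96, 120, 144), experimental stage and replicate index.
#' Stages follow the design: 0 h control, 24/48 h first stress (S1),
#' 96 h recovery (R), 120/144 h second stress (S2).
#'
#' @param path TSV with columns sample_id, time_h, stage, replicate.
#' @return data.frame, validated.
#' @export
readSampleSheet <- function(path) {
    sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    validateSampleSheet(sheet)
    sheet
}

#' Stage label implied by a sampling time
#'
#' @param time_h numeric vector of sampling times in hours.
#' @return character vector of stages: control, S1, R or S2.
#' @export
stageForTime <- function(time_h) {
    out <- rep(NA_character_, length(time_h))
    out[time_h == 0] <- "control"
    out[time_h %in% c(24, 48)] <- "S1"
    out[time_h == 96] <- "R"
    out[time_h %in% c(120, 144)] <- "S2"
    out
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet data.frame.
#' @export
validateSampleSheet <- function(sheet) {
    need <- c("sample_id", "time_h", "stage", "replicate")
    miss <- setdiff(need, names(sheet))
    if (length(miss)) stop("sample sheet missing column(s): ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id")
    expect <- stageForTime(sheet$time_h)
    bad <- which(is.na(expect) | sheet$stage != expect)
    if (length(bad)) stop("stage inconsistent with time_h for sample(s): ",
                          paste(sheet$sample_id[bad], collapse = ", "))
    invisible(sheet)
}

#' Read a count table
#'
#' @param path TSV whose first column is the entity (gene or miRNA) id and
#'   remaining columns are per-sample integer counts.
#' @return integer matrix, entities x samples.
#' @export
readCounts <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "numeric"
    m
}

#' Default contrast set of the repeated-stress design
#'
#' Every later sampling point against 0 h, plus the recovery stage (96 h)
#' against the second stress stage (120 h and 144 h).
#'
#' @param times sampling times present (default the full design).
#' @return list of length-2 numeric vectors c(reference, test).
#' @export
defaultContrasts <- function(times = c(0, 24, 48, 96, 120, 144)) {
    out <- lapply(setdiff(times, 0), function(t) c(0, t))
    if (all(c(96, 120) %in% times)) out <- c(out, list(c(96, 120)))
    if (all(c(96, 144) %in% times)) out <- c(out, list(c(96, 144)))
    out
}

#' Median-of-ratios size factors
#'
#' The standard count-normalisation: per sample, the median ratio of counts
#' to the per-entity geometric mean, over entities expressed in every
#' sample.
#'
#' @param counts entities x samples matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
sizeFactors <- function(counts) {
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use)) return(stats::setNames(rep(1, ncol(counts)),
                                          colnames(counts)))
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt)
        exp(stats::median(log(cnt) - logGeo[use])))
    sf
}

#' Simple differential-expression test for one contrast
#'
#' A deliberately plain caller used for simulated data so no external
#' differential tool is needed: median-of-ratios normalisation, log2 fold
#' change of group means with pseudocount 0.5, Welch t-test on
#' log2(normalised + 0.5), and Benjamini-Hochberg adjustment. It makes no
#' claim of equivalence with shrinkage-based negative-binomial callers;
#' externally produced statistics tables are first-class inputs to
#' [callDifferential()].
#'
#' @param counts entities x samples integer matrix.
#' @param sheet sample sheet (see [readSampleSheet()]).
#' @param contrast length-2 vector c(reference time, test time).
#' @param pseudocount added before log2 (default 0.5).
#' @return data.frame with columns entity_id, ref_time, test_time, log2fc,
#'   p_value, p_adj.
#' @export
simpleDeTest <- function(counts, sheet, contrast, pseudocount = 0.5) {
    stopifnot(length(contrast) == 2)
    refIdx <- match(sheet$sample_id[sheet$time_h == contrast[1]],
                    colnames(counts))
    tstIdx <- match(sheet$sample_id[sheet$time_h == contrast[2]],
                    colnames(counts))
    if (anyNA(refIdx) || anyNA(tstIdx))
        stop("sample sheet and count matrix disagree on sample ids")
    if (length(refIdx) < 2 || length(tstIdx) < 2)
        stop("each contrast group needs >= 2 samples")
    norm <- sweep(counts, 2, sizeFactors(counts), "/")
    mRef <- rowMeans(norm[, refIdx, drop = FALSE])
    mTst <- rowMeans(norm[, tstIdx, drop = FALSE])
    lfc <- log2(mTst + pseudocount) - log2(mRef + pseudocount)
    lnorm <- log2(norm + pseudocount)
    p <- vapply(seq_len(nrow(counts)), function(i) {
        a <- lnorm[i, refIdx]
        b <- lnorm[i, tstIdx]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
        stats::t.test(b, a, var.equal = FALSE)$p.value
    }, numeric(1))
    data.frame(entity_id = rownames(counts),
               ref_time = contrast[1], test_time = contrast[2],
               log2fc = lfc, p_value = p,
               p_adj = benjaminiHochberg(p),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the simple test over a set of contrasts
#'
#' @param counts entities x samples matrix.
#' @param sheet sample sheet.
#' @param contrasts list of c(ref, test) pairs
#'   (default [defaultContrasts()]).
#' @return one stacked statistics data.frame.
#' @export
differentialStats <- function(counts, sheet,
                              contrasts = defaultContrasts(
                                  sort(unique(sheet$time_h)))) {
    do.call(rbind, lapply(contrasts, function(ct)
        simpleDeTest(counts, sheet, ct)))
}

#' Apply the differential-entity thresholds
#'
#' Keeps entities with strictly |log2fc| > \code{lfcMin} and strictly
#' adjusted p < \code{alpha} -- the criteria defining differentially
#' expressed genes, miRNAs and target genes throughout the analysis.
#'
#' @param stats statistics table with columns entity_id, ref_time,
#'   test_time, log2fc, p_adj (one row per entity per contrast).
#' @param lfcMin minimum absolute log2 fold change, exclusive (default 1).
#' @param alpha adjusted-p cutoff, exclusive (default 0.05).
#' @return object of class \code{DifferentialSet}: list with
#'   \code{contrast} (NULL when several), \code{entity_ids},
#'   \code{lfc_min}, \code{alpha}, and \code{table} (the passing rows).
#' @export
callDifferential <- function(stats, lfcMin = 1.0, alpha = 0.05) {
    key <- paste(stats$entity_id, stats$ref_time, stats$test_time)
    if (anyDuplicated(key))
        stop("duplicate (entity, contrast) rows in statistics table")
    keep <- abs(stats$log2fc) > lfcMin & stats$p_adj < alpha
    keep[is.na(keep)] <- FALSE
    tab <- stats[keep, , drop = FALSE]
    rownames(tab) <- NULL
    ctr <- unique(stats[, c("ref_time", "test_time")])
    structure(list(
        contrast = if (nrow(ctr) == 1) c(ctr$ref_time, ctr$test_time) else NULL,
        entity_ids = unique(tab$entity_id),
        lfc_min = lfcMin, alpha = alpha, table = tab),
        class = "DifferentialSet")
}

#' @export
print.DifferentialSet <- function(x, ...) {
    cat("DifferentialSet:", length(x$entity_ids), "entities",
        if (!is.null(x$contrast)) sprintf("(%g h vs %g h)", x$contrast[1],
                                          x$contrast[2]) else
            "(multiple contrasts)",
        sprintf("[|log2FC| > %g, adj. p < %g]\n", x$lfc_min, x$alpha))
    invisible(x)
}

#' Differential entity ids at one contrast
#'
#' @param set a \code{DifferentialSet} (possibly multi-contrast).
#' @param refTime,testTime the contrast to extract.
#' @return character vector of entity ids.
#' @export
differentialAt <- function(set, refTime, testTime) {
    tab <- set$table
    unique(tab$entity_id[tab$ref_time == refTime &
                         tab$test_time == testTime])
}
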