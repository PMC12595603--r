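#' Load gene models from GFF3
#'
#' Reads a GFF3 annotation (features \code{gene}, \code{mRNA}, \code{exon},
#' \code{CDS}, \code{five_prime_UTR}, \code{three_prime_UTR}) into a
#' [GeneCatalog-class]. When a gene carries several transcripts the longest
#' one (by summed exon length) is kept as the representative. GFF3
#' coordinates are 1-based closed and are stored as such (GRanges
#' convention); the TSS is the span start on the + strand and the span end
#' on the - strand.
#'
#' Chromosome lengths are taken from \code{##sequence-region} pragmas when
#' present; a two-column TSV (chrom, length) may be supplied instead and
#' takes precedence.
#'
#' @param path path to a GFF3 file.
#' @param chromLengthsFile optional TSV with columns chrom and length.
#' @return a [GeneCatalog-class].
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(
#'   "##gff-version 3",
#'   "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tID=t1.e1;Parent=t1",
#'   "chr1\tsrc\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\tCDS\t1101\t1900\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\tthree_prime_UTR\t1901\t2000\t.\t+\t.\tParent=t1"), gff)
#' cat <- loadAnnotation(gff)
#' geneIds(cat)
#' @export
loadAnnotation <- function(path, chromLengthsFile = NULL) {
    stopifnot(file.exists(path))
    lines <- readLines(path)
    body <- !grepl("^\\s*(#|$)", lines)
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nf != 9L)) {
        bad <- which(body)[which(nf != 9L)[1L]]
        stop("malformed GFF3 line ", bad, ": expected 9 tab-separated fields")
    }

    chromLengths <- .sequenceRegionLengths(lines)
    if (!is.null(chromLengthsFile)) {
        cl <- utils::read.table(chromLengthsFile, header = FALSE, sep = "\t",
                                col.names = c("chrom", "length"),
                                stringsAsFactors = FALSE)
        chromLengths <- stats::setNames(as.numeric(cl$length),
                                        as.character(cl$chrom))
    }

    if (!any(body)) {
        return(.emptyCatalog(chromLengths))
    }

    gff <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gff$type)

    genes <- gff[type == "gene"]
    if (!length(genes)) return(.emptyCatalog(chromLengths))
    geneId <- as.character(genes$ID)
    geneName <- if (!is.null(genes$Name)) as.character(genes$Name) else
        rep(NA_character_, length(genes))

    parent1 <- function(gr) {
        p <- gr$Parent
        vapply(as.list(p), function(v) if (length(v)) v[[1L]] else
               NA_character_, character(1))
    }

    mrna <- gff[type == "mRNA"]
    mrnaParent <- parent1(mrna)
    mrnaId <- as.character(mrna$ID)

    childTypes <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
    kids <- gff[type %in% childTypes]
    kidParent <- parent1(kids)
    kidType <- as.character(kids$type)

    # pick the representative (longest) transcript per gene
    exonLenByTx <- tapply(width(kids)[kidType == "exon"],
                          kidParent[kidType == "exon"], sum)
    txLen <- exonLenByTx[mrnaId]
    txLen[is.na(txLen)] <- width(mrna)[is.na(txLen)]
    repTx <- rep(NA_character_, length(genes))
    names(repTx) <- geneId
    for (g in geneId) {
        sel <- which(mrnaParent == g)
        if (length(sel)) repTx[g] <- mrnaId[sel[which.max(txLen[sel])]]
    }

    # child-within-parent validation
    txSpan <- mrna
    names(txSpan) <- mrnaId
    for (i in seq_along(kids)) {
        p <- kidParent[i]
        if (!is.na(p) && p %in% mrnaId) {
            ts <- txSpan[p]
            if (start(kids)[i] < start(ts) || end(kids)[i] > end(ts)) {
                g <- mrnaParent[match(p, mrnaId)]
                stop("feature outside its transcript span for gene ", g)
            }
        }
    }
    gSpan <- genes
    names(gSpan) <- geneId
    for (i in seq_along(mrna)) {
        g <- mrnaParent[i]
        if (!is.na(g) && g %in% geneId) {
            gs <- gSpan[g]
            if (start(mrna)[i] < start(gs) || end(mrna)[i] > end(gs)) {
                stop("transcript outside its gene span for gene ", g)
            }
        }
    }

    partsList <- vector("list", length(genes))
    meta <- data.frame(
        gene_id = geneId, symbol = geneName,
        tss = ifelse(as.character(strand(genes)) == "-", end(genes),
                     start(genes)),
        tes = ifelse(as.character(strand(genes)) == "-", start(genes),
                     end(genes)),
        utr5_len = 0, cds_len = 0, utr3_len = 0, transcript_length = 0,
        stringsAsFactors = FALSE)

    for (i in seq_along(genes)) {
        tx <- repTx[geneId[i]]
        if (is.na(tx)) {
            # no transcript annotated: treat the full span as one exonic CDS
            pg <- GRanges(seqnames(genes)[i],
                          IRanges(start(genes)[i], end(genes)[i]),
                          strand = strand(genes)[i])
            pg <- rep(pg, 2L)
            mcols(pg)$gene_id <- geneId[i]
            mcols(pg)$feature <- c("exon", "CDS")
            partsList[[i]] <- pg
            meta$cds_len[i] <- width(genes)[i]
            meta$transcript_length[i] <- width(genes)[i]
            next
        }
        sel <- which(kidParent == tx)
        pg <- granges(kids[sel])
        mcols(pg)$gene_id <- geneId[i]
        mcols(pg)$feature <- kidType[sel]
        partsList[[i]] <- pg
        wsum <- function(f) sum(width(pg)[mcols(pg)$feature == f])
        meta$utr5_len[i] <- wsum("five_prime_UTR")
        meta$cds_len[i] <- wsum("CDS")
        meta$utr3_len[i] <- wsum("three_prime_UTR")
        nExon <- sum(mcols(pg)$feature == "exon")
        meta$transcript_length[i] <- if (nExon) wsum("exon") else
            meta$utr5_len[i] + meta$cds_len[i] + meta$utr3_len[i]
    }

    parts <- do.call(c, partsList)
    out <- granges(genes)
    mcols(out) <- DataFrame(meta)
    new("GeneCatalog", genes = out, parts = parts,
        chromLengths = chromLengths)
}

.sequenceRegionLengths <- function(lines) {
    sr <- grep("^##sequence-region", lines, value = TRUE)
    if (!length(sr)) return(stats::setNames(numeric(0), character(0)))
    f <- strsplit(sr, "\\s+")
    stats::setNames(vapply(f, function(x) as.numeric(x[4L]), numeric(1)),
                    vapply(f, function(x) x[2L], character(1)))
}

.emptyCatalog <- function(chromLengths = numeric(0)) {
    g <- GRanges()
    mcols(g) <- DataFrame(gene_id = character(0), symbol = character(0),
                          tss = numeric(0), tes = numeric(0),
                          utr5_len = numeric(0), cds_len = numeric(0),
                          utr3_len = numeric(0),
                          transcript_length = numeric(0))
    p <- GRanges()
    mcols(p) <- DataFrame(gene_id = character(0), feature = character(0))
    new("GeneCatalog", genes = g, parts = p, chromLengths = chromLengths)
}

#' Write a catalog back to GFF3
#'
#' Emits gene, mRNA and per-compartment features with the original 1-based
#' closed coordinates, so that \code{loadAnnotation(writeAnnotation(x))}
#' round-trips coordinates exactly.
#'
#' @param catalog a [GeneCatalog-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeAnnotation <- function(catalog, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    cl <- chromLengths(catalog)
    for (ch in names(cl)) {
        if (!is.na(cl[[ch]]))
            writeLines(sprintf("##sequence-region %s 1 %d", ch,
                               as.integer(cl[[ch]])), con)
    }
    g <- geneRanges(catalog)
    p <- geneParts(catalog)
    fmt <- function(chrom, src, type, s, e, strand, attrs) {
        sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type,
                as.integer(s), as.integer(e), strand, attrs)
    }
    for (i in seq_along(g)) {
        id <- names(g)[i]
        chrom <- as.character(seqnames(g))[i]
        str <- as.character(strand(g))[i]
        sym <- mcols(g)$symbol[i]
        gAttr <- paste0("ID=", id,
                        if (!is.na(sym)) paste0(";Name=", sym) else "")
        writeLines(fmt(chrom, "epistress", "gene", start(g)[i], end(g)[i],
                       str, gAttr), con)
        tid <- paste0(id, ".t1")
        writeLines(fmt(chrom, "epistress", "mRNA", start(g)[i], end(g)[i],
                       str, paste0("ID=", tid, ";Parent=", id)), con)
        sel <- which(mcols(p)$gene_id == id)
        sel <- sel[order(start(p)[sel], mcols(p)$feature[sel])]
        for (j in sel) {
            writeLines(fmt(chrom, "epistress",
                           mcols(p)$feature[j], start(p)[j], end(p)[j],
                           str, paste0("Parent=", tid)), con)
        }
    }
    invisible(path)
}

#' Promoter windows upstream of the TSS
#'
#' The promoter is the \code{upstream} bases 5' of the TSS in transcription
#' orientation: \code{[tss - upstream, tss)} on the + strand and
#' \code{(tes, tes + upstream]} in genomic coordinates on the - strand,
#' clipped at chromosome boundaries when lengths are known. Setting
#' \code{strandAware = FALSE} always takes the genomic-left window instead.
#'
#' @param catalog a [GeneCatalog-class].
#' @param upstream window size in bases (default 2000).
#' @param strandAware honour transcription orientation (default TRUE).
#' @return named \code{GRanges}, one (possibly zero-width-clipped) promoter
#'   per gene, in catalog order.
#' @export
promoterRegions <- function(catalog, upstream = 2000, strandAware = TRUE) {
    stopifnot(upstream > 0)
    g <- geneRanges(catalog)
    if (!length(g)) return(g)
    if (strandAware) {
        pr <- GenomicRanges::promoters(g, upstream = upstream,
                                       downstream = 0)
    } else {
        pr <- GRanges(seqnames(g),
                      IRanges(start(g) - upstream, width = upstream),
                      strand = strand(g))
        names(pr) <- names(g)
    }
    # clip to [1, chrom length]
    s <- pmax(start(pr), 1L)
    cl <- chromLengths(catalog)
    e <- end(pr)
    if (length(cl)) {
        chr <- as.character(seqnames(pr))
        lim <- cl[chr]
        ok <- !is.na(lim)
        e[ok] <- pmin(e[ok], lim[ok])
    }
    e <- pmax(e, s - 1L)  # zero-width when fully off-contig
    out <- GRanges(seqnames(pr), IRanges(s, e), strand = strand(pr))
    names(out) <- names(pr)
    out
}

#' Gene-body windows (TSS through TES)
#'
#' The gene body is the full genomic span from the transcription start site
#' to the transcription end site, introns included; identical for both
#' strands.
#'
#' @param catalog a [GeneCatalog-class].
#' @return named \code{GRanges} of gene spans.
#' @export
geneBodyRegions <- function(catalog) geneRanges(catalog)

#' Assign a genomic position to promoter / gene body / none for one gene
#'
#' Positions are 1-based. A position exactly at the TSS belongs to the gene
#' body (the promoter stops one base 5' of the TSS); gene body wins over
#' promoter should the two ever touch.
#'
#' @param catalog a [GeneCatalog-class].
#' @param geneId gene identifier.
#' @param chrom chromosome of the site.
#' @param pos 1-based position of the site.
#' @param upstream promoter size (default 2000).
#' @param strandAware see [promoterRegions()].
#' @return one of \code{"gene_body"}, \code{"promoter"}, \code{"none"}.
#' @export
assignSiteLocation <- function(catalog, geneId, chrom, pos, upstream = 2000,
                               strandAware = TRUE) {
    stopifnot(pos >= 1)
    g <- geneRanges(catalog)
    i <- match(geneId, names(g))
    if (is.na(i)) stop("unknown gene_id: ", geneId)
    if (chrom != as.character(seqnames(g))[i]) return("none")
    if (pos >= start(g)[i] && pos <= end(g)[i]) return("gene_body")
    # promoter window by direct arithmetic (same convention as
    # promoterRegions, cheap for single lookups)
    minus <- strandAware && as.character(strand(g))[i] == "-"
    if (minus) {
        prS <- end(g)[i] + 1
        prE <- end(g)[i] + upstream
        cl <- chromLengths(catalog)
        if (chrom %in% names(cl) && !is.na(cl[[chrom]]))
            prE <- min(prE, cl[[chrom]])
    } else {
        prS <- max(1, start(g)[i] - upstream)
        prE <- start(g)[i] - 1
    }
    if (prS <= prE && pos >= prS && pos <= prE) return("promoter")
    "none"
}

#' Map sites to all overlapping promoters and gene bodies
#'
#' A site falling in the promoter of one gene and the body of another is
#' assigned to both genes independently, one row each.
#'
#' @param catalog a [GeneCatalog-class].
#' @param sites \code{GRanges} (width-1 positions) or a data.frame with
#'   columns \code{chrom} and \code{pos} (1-based).
#' @param upstream promoter size (default 2000).
#' @param strandAware see [promoterRegions()].
#' @return data.frame with columns \code{site_index}, \code{chrom},
#'   \code{pos}, \code{gene_id}, \code{location}.
#' @export
siteGeneOverlaps <- function(catalog, sites, upstream = 2000,
                             strandAware = TRUE) {
    if (is.data.frame(sites)) {
        sites <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
    }
    body <- geneBodyRegions(catalog)
    prom <- promoterRegions(catalog, upstream = upstream,
                            strandAware = strandAware)
    # seqlevel merging across query and subject is informational here
    hitsB <- suppressWarnings(
        GenomicRanges::findOverlaps(sites, body, ignore.strand = TRUE))
    hitsP <- suppressWarnings(
        GenomicRanges::findOverlaps(sites, prom, ignore.strand = TRUE))
    # gene body wins within the same gene
    keyB <- paste(S4Vectors::queryHits(hitsB), names(body)[S4Vectors::subjectHits(hitsB)])
    keyP <- paste(S4Vectors::queryHits(hitsP), names(prom)[S4Vectors::subjectHits(hitsP)])
    keepP <- !(keyP %in% keyB)
    out <- data.frame(
        site_index = c(S4Vectors::queryHits(hitsB),
                       S4Vectors::queryHits(hitsP)[keepP]),
        gene_id = c(names(body)[S4Vectors::subjectHits(hitsB)],
                    names(prom)[S4Vectors::subjectHits(hitsP)][keepP]),
        location = c(rep("gene_body", length(hitsB)),
                     rep("promoter", sum(keepP))),
        stringsAsFactors = FALSE)
    out$chrom <- as.character(seqnames(sites))[out$site_index]
    out$pos <- start(sites)[out$site_index]
    out <- out[order(out$site_index, out$gene_id), c("site_index", "chrom",
                                                     "pos", "gene_id",
                                                     "location")]
    rownames(out) <- NULL
    out
}

#' Transcript compartment boundaries of a gene
#'
#' Returns the half-open transcript-coordinate intervals (0-based) of the
#' 5'UTR, CDS and 3'UTR in transcription order.
#'
#' @param catalog a [GeneCatalog-class].
#' @param geneId gene identifier.
#' @return data.frame with columns \code{region}, \code{t_start},
#'   \code{t_end} (0-based half-open).
#' @export
transcriptCompartments <- function(catalog, geneId) {
    g <- geneRanges(catalog)
    i <- match(geneId, names(g))
    if (is.na(i)) stop("unknown gene_id: ", geneId)
    l5 <- mcols(g)$utr5_len[i]
    lc <- mcols(g)$cds_len[i]
    l3 <- mcols(g)$utr3_len[i]
    data.frame(region = c("utr5", "cds", "utr3"),
               t_start = c(0, l5, l5 + lc),
               t_end = c(l5, l5 + lc, l5 + lc + l3),
               stringsAsFactors = FALSE)
}

#' Assign a transcript-coordinate binding interval to a compartment
#'
#' The label is the compartment (5'UTR, CDS, 3'UTR) with the largest base
#' overlap with the binding interval; ties break 3'UTR > CDS > 5'UTR, the
#' canonical priority of miRNA binding biology.
#'
#' @param catalog a [GeneCatalog-class].
#' @param geneId gene identifier.
#' @param tStart binding start in transcript coordinates, 0-based.
#' @param tEnd binding end, exclusive (half-open interval).
#' @return one of \code{"utr5"}, \code{"cds"}, \code{"utr3"}.
#' @export
assignBindingRegion <- function(catalog, geneId, tStart, tEnd) {
    comp <- transcriptCompartments(catalog, geneId)
    total <- comp$t_end[3L]
    if (tStart < 0 || tEnd > total || tStart >= tEnd) {
        stop("binding interval [", tStart, ", ", tEnd,
             ") outside transcript [0, ", total, ") of gene ", geneId)
    }
    ov <- pmax(0, pmin(tEnd, comp$t_end) - pmax(tStart, comp$t_start))
    names(ov) <- comp$region
    priority <- c(utr3 = 3, cds = 2, utr5 = 1)
    best <- names(ov)[ov == max(ov)]
    best[which.max(priority[best])]
}
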