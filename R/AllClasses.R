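#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

#' Strand-aware gene model catalog
#'
#' A \code{GeneCatalog} holds one representative transcript per gene:
#' the genomic gene span (TSS through TES, introns included), the
#' transcript compartment pieces (exon, 5'UTR, CDS, 3'UTR) as genomic
#' ranges, and optional chromosome lengths used to clip promoter windows
#' at contig boundaries.
#'
#' Gene-level metadata lives in \code{mcols(geneRanges(x))}: \code{gene_id},
#' \code{symbol}, \code{tss}, \code{tes} (1-based genomic positions,
#' strand-aware), compartment lengths \code{utr5_len}, \code{cds_len},
#' \code{utr3_len} and \code{transcript_length}.
#'
#' @slot genes \code{GRanges} of gene spans with the metadata above.
#' @slot parts \code{GRanges} of per-gene feature pieces with metadata
#'   columns \code{gene_id} and \code{feature} (one of \code{exon},
#'   \code{five_prime_UTR}, \code{CDS}, \code{three_prime_UTR}).
#' @slot chromLengths named numeric vector of chromosome lengths, possibly
#'   \code{NA} when unknown.
#'
#' @seealso [loadAnnotation()], [promoterRegions()], [assignSiteLocation()]
#' @export
setClass("GeneCatalog",
    representation(
        genes = "GRanges",
        parts = "GRanges",
        chromLengths = "numeric"
    )
)

setValidity("GeneCatalog", function(object) {
    msg <- character()
    ids <- mcols(object@genes)$gene_id
    if (is.null(ids)) {
        msg <- c(msg, "genes must carry a 'gene_id' metadata column")
    } else if (anyDuplicated(ids)) {
        msg <- c(msg, "duplicated gene_id in catalog")
    }
    need <- c("symbol", "tss", "tes", "utr5_len", "cds_len", "utr3_len",
              "transcript_length")
    miss <- setdiff(need, colnames(mcols(object@genes)))
    if (length(miss)) {
        msg <- c(msg, paste0("genes missing metadata column(s): ",
                             paste(miss, collapse = ", ")))
    }
    cl <- object@chromLengths
    if (length(cl) && length(object@genes)) {
        chr <- as.character(seqnames(object@genes))
        known <- chr %in% names(cl) & !is.na(cl[chr])
        if (any(known)) {
            bad <- which(known & end(object@genes) > cl[chr])
            if (length(bad)) {
                msg <- c(msg, paste0("gene span exceeds chromosome length: ",
                                     paste(ids[bad], collapse = ", ")))
            }
        }
    }
    if (length(object@parts)) {
        pid <- mcols(object@parts)$gene_id
        if (is.null(pid) || is.null(mcols(object@parts)$feature)) {
            msg <- c(msg, "parts must carry 'gene_id' and 'feature' columns")
        } else if (!all(pid %in% ids)) {
            msg <- c(msg, "parts refer to unknown gene_id")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Monte-Carlo dual-regulation permutation result
#'
#' Result of the permutation test asking whether the observed number of
#' genes carrying both miRNA-target evidence and differential-methylation
#' evidence exceeds what independent draws of equally sized gene sets from
#' the same universe would produce.
#'
#' @slot universeSize number of genes the sets are drawn from.
#' @slot nMirna size of the miRNA-regulated set.
#' @slot nMeth size of the methylation-regulated set.
#' @slot observedOverlap observed number of dually regulated genes.
#' @slot iterations number of Monte-Carlo iterations.
#' @slot nullOverlaps integer vector of null overlaps, one per iteration.
#' @slot pEmpirical add-one empirical p-value,
#'   \eqn{(1 + \#\{null \ge obs\}) / (iterations + 1)}.
#' @slot seed integer seed used for the draws (NA when none supplied).
#'
#' @seealso [dualRegulationPermutation()]
#' @export
setClass("PermutationResult",
    representation(
        universeSize = "integer",
        nMirna = "integer",
        nMeth = "integer",
        observedOverlap = "integer",
        iterations = "integer",
        nullOverlaps = "integer",
        pEmpirical = "numeric",
        seed = "integer"
    )
)

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (length(object@nullOverlaps) != object@iterations)
        msg <- c(msg, "length(nullOverlaps) must equal iterations")
    if (object@observedOverlap < 0L ||
        object@observedOverlap > min(object@nMirna, object@nMeth))
        msg <- c(msg, "observedOverlap outside [0, min(nMirna, nMeth)]")
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
        msg <- c(msg, "pEmpirical must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneCatalog number of genes in the catalog
#' @param x a \code{GeneCatalog}
#' @export
nGenes <- function(x) length(x@genes)

#' @describeIn GeneCatalog gene identifiers
#' @export
geneIds <- function(x) as.character(mcols(x@genes)$gene_id)

#' @describeIn GeneCatalog gene spans as a named \code{GRanges}
#' @export
geneRanges <- function(x) {
    gr <- x@genes
    names(gr) <- mcols(gr)$gene_id
    gr
}

#' @describeIn GeneCatalog compartment/exon pieces as \code{GRanges}
#' @export
geneParts <- function(x) x@parts

#' @describeIn GeneCatalog chromosome lengths (possibly NA)
#' @export
chromLengths <- function(x) x@chromLengths

setMethod("show", "GeneCatalog", function(object) {
    cat("GeneCatalog with", length(object@genes), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "sequence(s)\n")
    if (length(object@genes)) {
        ids <- geneIds(object)
        cat("  gene_id:", paste(utils::head(ids, 3), collapse = ", "),
            if (length(ids) > 3) "..." else "", "\n")
    }
    cat("  chromLengths:",
        if (length(object@chromLengths)) paste0(length(object@chromLengths),
                                                " provided") else "none",
        "\n")
})

#' @describeIn PermutationResult add-one empirical p-value
#' @param x a \code{PermutationResult}
#' @export
empiricalP <- function(x) x@pEmpirical

#' @describeIn PermutationResult observed dual-regulation overlap
#' @export
observedOverlap <- function(x) x@observedOverlap

#' @describeIn PermutationResult null overlap draws (one per iteration)
#' @export
nullOverlaps <- function(x) x@nullOverlaps

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult:",
        sprintf("N = %d, nA = %d (miRNA), nB = %d (methylation)\n",
                object@universeSize, object@nMirna, object@nMeth))
    cat(sprintf("  observed overlap = %d; null mean = %.2f over %d iterations\n",
                object@observedOverlap, mean(object@nullOverlaps),
                object@iterations))
    cat(sprintf("  empirical p = %.4g (add-one convention)\n",
                object@pEmpirical))
})
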