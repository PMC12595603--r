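.TABLE1_MD5 <- "1066f9d37ebd8ad4b14dc97d3cb5c714"

#' Osmotic-strategy pathway implied by a function annotation
#'
#' Maps free-text function labels onto the three canonical osmotic
#' strategies: water transport, ion transport, and free-amino-acid (FAA)
#' metabolism and biogenesis. Amino-acid transporters (L-cystine
#' transport) belong to the FAA strategy; all other transport labels are
#' ion transport; everything else (amino-acid and related metabolism) is
#' FAA.
#'
#' @param label character vector of function annotations.
#' @return character vector: \code{"water"}, \code{"ion"} or
#'   \code{"faa"}.
#' @export
pathwayFromFunction <- function(label) {
    low <- tolower(label)
    ifelse(grepl("water", low), "water",
    ifelse(grepl("transport", low) & !grepl("cystine", low), "ion",
           "faa"))
}

#' Load the packaged DMSG fixture
#'
#' The packaged table of methylation-related stress-responsive genes
#' (22 records: gene, methylation site, promoter/gene-body location,
#' difference direction, methylation-expression correlation sign and
#' function annotation). The file's checksum is verified before use.
#'
#' @param path fixture path (default: the packaged copy).
#' @return data.frame with a derived \code{pathway} column.
#' @export
readTable1Fixture <- function(path = system.file("extdata",
                                                 "table1_dmsgs.tsv",
                                                 package = "epistress")) {
    if (!file.exists(path)) stop("fixture not found: ", path)
    if (unname(tools::md5sum(path)) != .TABLE1_MD5)
        stop("fixture checksum mismatch: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            quote = "", stringsAsFactors = FALSE)
    df$pathway <- pathwayFromFunction(df$function_label)
    df
}

#' Summaries of the packaged DMSG table
#'
#' Per-pathway gene counts, promoter/gene-body fractions, and
#' direction/correlation tallies of the packaged DMSG records.
#'
#' @param path fixture path (default: the packaged copy).
#' @return list with \code{n_records}, \code{pathway_counts} (genes per
#'   pathway), \code{location_counts} and \code{location_fractions}
#'   (per pathway), \code{direction_counts} and
#'   \code{correlation_counts} (per pathway x level).
#' @export
summarizeTable1Fixture <- function(path = system.file("extdata",
                                                      "table1_dmsgs.tsv",
                                                      package = "epistress")) {
    df <- readTable1Fixture(path)
    byPath <- split(df, df$pathway)
    locCounts <- lapply(byPath, function(d) table(d$location))
    list(
        n_records = nrow(df),
        pathway_counts = vapply(byPath, function(d)
            length(unique(d$gene_id)), integer(1)),
        location_counts = locCounts,
        location_fractions = lapply(locCounts, function(tb)
            stats::setNames(as.numeric(tb) / sum(tb), names(tb))),
        direction_counts = table(df$pathway, df$diff_methy),
        correlation_counts = table(df$pathway, df$correlation))
}
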