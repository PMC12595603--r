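# Programmatic fixtures: GFF3 text built in code, loaded through the
# package's own reader.

# genes: data.frame(chrom, start, end, strand, id, l5, lc, l3, name)
# single-exon genes whose compartments tile the span in transcription
# orientation (5'UTR at the genomic right for - strand genes)
toyGff3 <- function(genes, chromLengths = NULL) {
    lines <- "##gff-version 3"
    if (!is.null(chromLengths)) {
        lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                                  names(chromLengths),
                                  as.integer(chromLengths)))
    }
    for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        nm <- if (!is.null(g$name) && !is.na(g$name))
            paste0(";Name=", g$name) else ""
        tid <- paste0(g$id, ".t1")
        lines <- c(lines,
            sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                    g$chrom, g$start, g$end, g$strand, g$id, nm),
            sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                    g$chrom, g$start, g$end, g$strand, tid, g$id),
            sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    g$chrom, g$start, g$end, g$strand, tid))
        firstLen <- if (g$strand == "+") g$l5 else g$l3
        b1 <- g$start
        e1 <- g$start + firstLen - 1
        b2 <- e1 + 1
        e2 <- b2 + g$lc - 1
        b3 <- e2 + 1
        e3 <- g$end
        feats <- if (g$strand == "+")
            c("five_prime_UTR", "CDS", "three_prime_UTR") else
            c("three_prime_UTR", "CDS", "five_prime_UTR")
        lines <- c(lines,
            sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
                    g$chrom, feats, c(b1, b2, b3), c(e1, e2, e3),
                    g$strand, tid))
    }
    lines
}

toyCatalog <- function(genes, chromLengths = NULL) {
    f <- tempfile(fileext = ".gff3")
    writeLines(toyGff3(genes, chromLengths), f)
    loadAnnotation(f)
}

# a quick random catalog for property tests
randomCatalog <- function(n = 40, seed = 1) {
    set.seed(seed)
    l5 <- sample(80:300, n, replace = TRUE)
    lc <- sample(600:1500, n, replace = TRUE)
    l3 <- sample(150:500, n, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    genes <- do.call(rbind, lapply(split(seq_len(n), chrom), function(ii) {
        len <- (l5 + lc + l3)[ii]
        gap <- 2500 + sample(0:1500, length(ii), replace = TRUE)
        start <- integer(length(ii))
        cur <- 1L
        for (j in seq_along(ii)) {
            start[j] <- cur + gap[j]
            cur <- start[j] + len[j]
        }
        data.frame(chrom = chrom[ii][1], start = start,
                   end = start + (l5 + lc + l3)[ii] - 1,
                   strand = sample(c("+", "-"), length(ii),
                                   replace = TRUE),
                   id = sprintf("%s_g%02d", chrom[ii][1],
                                seq_along(ii)),
                   l5 = l5[ii], lc = lc[ii], l3 = l3[ii],
                   name = NA_character_, stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL
    list(genes = genes,
         catalog = toyCatalog(genes,
                              c(chr1 = 5e6, chr2 = 5e6)))
}

# sample sheet of the repeated-stress design
toySheet <- function(times = c(0, 24, 48, 96, 120, 144),
                     replicates = c(6, 4, 6, 4, 4, 3)) {
    do.call(rbind, lapply(seq_along(times), function(i)
        data.frame(sample_id = sprintf("T%03d_r%d", times[i],
                                       seq_len(replicates[i])),
                   time_h = times[i], stage = stageForTime(times[i]),
                   replicate = seq_len(replicates[i]),
                   stringsAsFactors = FALSE)))
}

# catalog + site set re-expressing the packaged DMSG table: one gene per
# record, laid out so each site falls in the stated compartment
table1Scenario <- function() {
    df <- readTable1Fixture()
    parts <- strsplit(df$methy_site, ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1)
    pos <- as.integer(vapply(parts, `[`, character(1), 2))
    # + strand genes of width 3000: promoter sites 100 bp upstream of the
    # TSS, gene-body sites 500 bp into the span
    start <- ifelse(df$location == "Promoter", pos + 100, pos - 500)
    genes <- data.frame(chrom = chrom, start = start,
                        end = start + 2999, strand = "+",
                        id = df$gene_id, l5 = 200, lc = 2000, l3 = 800,
                        name = df$gene_name, stringsAsFactors = FALSE)
    functional <- data.frame(gene_id = df$gene_id,
                             symbol = df$gene_name,
                             pathway = df$pathway,
                             stringsAsFactors = FALSE)
    sites <- data.frame(chrom = chrom, pos = pos,
                        meth_diff = ifelse(df$diff_methy == "Up", 40,
                                           -40),
                        direction = tolower(df$diff_methy),
                        stringsAsFactors = FALSE)
    list(table = df, catalog = toyCatalog(genes), sites = sites,
         functional = functional)
}
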