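test_that("GFF3 loading converts coordinates and builds gene models", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3"), f)
    expect_equal(nGenes(loadAnnotation(f)), 0)

    genes <- data.frame(chrom = "chr1", start = 1001, end = 2000,
                        strand = "+", id = "g1", l5 = 100, lc = 800,
                        l3 = 100, name = "KCNK16",
                        stringsAsFactors = FALSE)
    cat1 <- toyCatalog(genes)
    g <- geneRanges(cat1)
    expect_equal(names(g), "g1")
    expect_equal(start(g), 1001)
    expect_equal(end(g), 2000)
    expect_equal(S4Vectors::mcols(g)$tss, 1001)
    expect_equal(S4Vectors::mcols(g)$symbol, "KCNK16")
    expect_equal(S4Vectors::mcols(g)$transcript_length, 1000)
})

test_that("malformed GFF3 lines are rejected with their line number", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\ttoy\tgene\t100\t200\t.\t+\t.\tID=g1",
                 "chr1\ttoy\tgene\t300\t400"), f)
    expect_error(loadAnnotation(f), "line 3")
})

test_that("features outside their parent span fail validation by gene", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\ttoy\tgene\t1000\t2000\t.\t+\t.\tID=gBad",
        "chr1\ttoy\tmRNA\t1000\t2000\t.\t+\t.\tID=tBad;Parent=gBad",
        "chr1\ttoy\texon\t900\t2000\t.\t+\t.\tParent=tBad"), f)
    expect_error(loadAnnotation(f), "gBad")
})

test_that("multi-exon and multi-transcript genes resolve to the longest transcript", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        # - strand gene with two exons (lengths 301 + 200 = 501)
        "chr2\ttoy\tgene\t5000\t6200\t.\t-\t.\tID=gm",
        "chr2\ttoy\tmRNA\t5000\t6200\t.\t-\t.\tID=tm;Parent=gm",
        "chr2\ttoy\texon\t5000\t5300\t.\t-\t.\tParent=tm",
        "chr2\ttoy\texon\t6001\t6200\t.\t-\t.\tParent=tm",
        "chr2\ttoy\tCDS\t5000\t5300\t.\t-\t.\tParent=tm",
        "chr2\ttoy\tCDS\t6001\t6200\t.\t-\t.\tParent=tm",
        # gene with a short and a long transcript
        "chr2\ttoy\tgene\t9000\t9900\t.\t+\t.\tID=g2",
        "chr2\ttoy\tmRNA\t9000\t9400\t.\t+\t.\tID=t2a;Parent=g2",
        "chr2\ttoy\texon\t9000\t9400\t.\t+\t.\tParent=t2a",
        "chr2\ttoy\tmRNA\t9000\t9900\t.\t+\t.\tID=t2b;Parent=g2",
        "chr2\ttoy\texon\t9000\t9900\t.\t+\t.\tParent=t2b"), f)
    cat2 <- loadAnnotation(f)
    m <- S4Vectors::mcols(geneRanges(cat2))
    # hand-summed exon lengths
    expect_equal(m$transcript_length[m$gene_id == "gm"], 301 + 200)
    expect_equal(m$tss[m$gene_id == "gm"], 6200)
    expect_equal(m$transcript_length[m$gene_id == "g2"], 901)
})

test_that("GFF3 round-trips through the writer with identical coordinates", {
    rc <- randomCatalog(n = 12, seed = 42)
    out <- tempfile(fileext = ".gff3")
    writeAnnotation(rc$catalog, out)
    back <- loadAnnotation(out)
    g1 <- geneRanges(rc$catalog)
    g2 <- geneRanges(back)
    expect_equal(names(g1), names(g2))
    expect_equal(start(g1), start(g2))
    expect_equal(end(g1), end(g2))
    expect_equal(as.character(GenomicRanges::strand(g1)),
                 as.character(GenomicRanges::strand(g2)))
    m1 <- S4Vectors::mcols(g1)
    m2 <- S4Vectors::mcols(g2)
    for (col in c("tss", "tes", "utr5_len", "cds_len", "utr3_len",
                  "transcript_length")) {
        expect_equal(as.vector(m1[[col]]), as.vector(m2[[col]]),
                     info = col)
    }
})

test_that("promoter windows are strand-aware, 2 kb, and clipped", {
    genes <- data.frame(
        chrom = c("chr1", "chr1", "chr1"),
        start = c(5001, 2001, 101),
        end = c(6000, 5000, 600),
        strand = c("+", "-", "+"),
        id = c("plus", "minus", "edge"),
        l5 = 100, lc = c(700, 700, 300),
        l3 = c(200, 2200, 100),
        name = NA_character_, stringsAsFactors = FALSE)
    cat3 <- toyCatalog(genes, c(chr1 = 6500))
    pr <- promoterRegions(cat3)
    # + strand: the 2000 bases left of the TSS
    expect_equal(start(pr)[1], 3001)
    expect_equal(end(pr)[1], 5000)
    # - strand: the 2000 bases right of the genomic end
    expect_equal(start(pr)[2], 5001)
    expect_equal(end(pr)[2], 6500)  # clipped at the chromosome end
    # clipped at the chromosome start
    expect_equal(start(pr)[3], 1)
    expect_equal(end(pr)[3], 100)
    expect_equal(width(pr)[3], 100)
    # strand-agnostic mode always takes the genomic-left window
    prL <- promoterRegions(cat3, strandAware = FALSE)
    expect_equal(start(prL)[2], 1)
    expect_equal(end(prL)[2], 2000)
    # gene body is the unstranded span
    gb <- geneBodyRegions(cat3)
    expect_equal(start(gb)[2], 2001)
    expect_equal(end(gb)[2], 5000)
})

test_that("promoters and gene bodies are disjoint and at most 2 kb", {
    rc <- randomCatalog(n = 40, seed = 7)
    pr <- promoterRegions(rc$catalog)
    gb <- geneBodyRegions(rc$catalog)
    hits <- GenomicRanges::findOverlaps(pr, gb, ignore.strand = TRUE)
    self <- S4Vectors::queryHits(hits) == S4Vectors::subjectHits(hits)
    expect_false(any(self))
    expect_true(all(width(pr) <= 2000))
    roomy <- start(gb) > 2000
    expect_true(all(width(pr)[roomy] == 2000))
})

test_that("site location matches the brute-force scan and TSS is gene body", {
    rc <- randomCatalog(n = 30, seed = 11)
    g <- geneRanges(rc$catalog)
    m <- S4Vectors::mcols(g)
    set.seed(12)
    n <- 2000
    gi <- sample(length(g), n, replace = TRUE)
    pos <- pmax(1, start(g)[gi] + sample((-2500):3500, n, replace = TRUE))
    got <- vapply(seq_len(n), function(j)
        assignSiteLocation(rc$catalog, names(g)[gi[j]],
                           as.character(GenomicRanges::seqnames(g))[gi[j]],
                           pos[j]), character(1))
    want <- vapply(seq_len(n), function(j)
        oracleSiteLocation(as.character(GenomicRanges::seqnames(g))[gi[j]],
                           pos[j],
                           as.character(GenomicRanges::seqnames(g))[gi[j]],
                           start(g)[gi[j]], end(g)[gi[j]],
                           as.character(GenomicRanges::strand(g))[gi[j]],
                           chromLen = chromLengths(rc$catalog)[[
                               as.character(GenomicRanges::seqnames(g))[gi[j]]]]),
        character(1))
    expect_identical(got, want)
    # a position exactly at the TSS belongs to the gene body
    plus <- which(as.character(GenomicRanges::strand(g)) == "+")[1]
    expect_identical(
        assignSiteLocation(rc$catalog, names(g)[plus],
                           as.character(GenomicRanges::seqnames(g))[plus],
                           m$tss[plus]),
        "gene_body")
    expect_identical(
        assignSiteLocation(rc$catalog, names(g)[plus],
                           as.character(GenomicRanges::seqnames(g))[plus],
                           m$tss[plus] - 1),
        "promoter")
})

test_that("a site can belong to two overlapping genes independently", {
    genes <- data.frame(
        chrom = "chr1",
        start = c(10000, 13500), end = c(13000, 16000),
        strand = "+", id = c("gA", "gB"),
        l5 = 100, lc = 2000, l3 = c(901, 401),
        name = NA_character_, stringsAsFactors = FALSE)
    cat4 <- toyCatalog(genes)
    # 12000 is inside gA's body and inside gB's promoter [11500, 13499]
    ov <- siteGeneOverlaps(cat4, data.frame(chrom = "chr1", pos = 12000))
    expect_equal(sort(ov$gene_id), c("gA", "gB"))
    expect_equal(ov$location[ov$gene_id == "gA"], "gene_body")
    expect_equal(ov$location[ov$gene_id == "gB"], "promoter")
})

test_that("binding regions follow majority overlap with 3'UTR-first ties", {
    genes <- data.frame(chrom = "chr1", start = 1001, end = 2000,
                        strand = "+", id = "g1", l5 = 100, lc = 700,
                        l3 = 200, name = NA_character_,
                        stringsAsFactors = FALSE)
    cat5 <- toyCatalog(genes)
    expect_equal(assignBindingRegion(cat5, "g1", 200, 222), "cds")
    # 4 bases in CDS, 18 in 3'UTR -> majority 3'UTR
    expect_equal(assignBindingRegion(cat5, "g1", 796, 818), "utr3")
    expect_error(assignBindingRegion(cat5, "g1", 990, 1011), "outside")
    # randomized intervals against the per-base counting oracle
    set.seed(3)
    for (i in 1:300) {
        s <- sample(0:979, 1)
        e <- s + sample(1:21, 1)
        expect_equal(assignBindingRegion(cat5, "g1", s, e),
                     oracleBindingRegion(s, e, 100, 700, 200))
    }
})
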