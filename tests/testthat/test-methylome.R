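methTable <- function(chrom, pos, meth, unmeth, strand = "+") {
    data.frame(chrom = chrom, pos = pos, strand = strand,
               meth_count = meth, unmeth_count = unmeth,
               stringsAsFactors = FALSE)
}

twoGroupSheet <- function(nA = 3, nB = 3) {
    data.frame(sample_id = c(sprintf("A%d", seq_len(nA)),
                             sprintf("B%d", seq_len(nB))),
               time_h = rep(c(0, 24), c(nA, nB)),
               stage = rep(c("control", "S1"), c(nA, nB)),
               replicate = c(seq_len(nA), seq_len(nB)),
               stringsAsFactors = FALSE)
}

test_that("methylation loading enforces coverage in every sample", {
    sheet <- twoGroupSheet(2, 2)
    pos <- seq(100, 2000, by = 100)  # 20 sites
    tabs <- lapply(seq_len(4), function(i)
        methTable("chr1", pos, meth = rep(8, 20), unmeth = rep(12, 20)))
    names(tabs) <- sheet$sample_id
    # drop coverage of site 5 in one sample below threshold
    tabs[[3]]$unmeth_count[5] <- 1
    se <- methylationCallsFromTables(tabs, sheet, minCoverage = 10)
    expect_equal(nrow(se), 19)
    kept <- GenomicRanges::start(SummarizedExperiment::rowRanges(se))
    expect_false(pos[5] %in% kept)
    # all covered -> all retained
    se2 <- methylationCallsFromTables(tabs, sheet, minCoverage = 5)
    expect_equal(nrow(se2), 20)
    # exact hand-filtered agreement
    cov <- sapply(tabs, function(tb) tb$meth_count + tb$unmeth_count)
    handKept <- pos[apply(cov >= 10, 1, all)]
    expect_setequal(kept, handKept)
})

test_that("duplicated coordinates with conflicting strand are rejected", {
    sheet <- twoGroupSheet(1, 1)
    f1 <- tempfile()
    f2 <- tempfile()
    tb <- methTable("chr1", c(100, 100), meth = c(5, 6),
                    unmeth = c(10, 10), strand = c("+", "-"))
    utils::write.table(tb, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(tb[1, ], f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    expect_error(loadMethylationCalls(c(A1 = f1, B1 = f2), sheet),
                 "conflicting strand")
})

test_that("symmetric CpG pairs merge onto the plus strand when asked", {
    sheet <- twoGroupSheet(1, 1)
    tabs <- list(
        A1 = methTable("chr1", c(100, 101, 300),
                       meth = c(10, 6, 20), unmeth = c(10, 14, 10),
                       strand = c("+", "-", "+")),
        B1 = methTable("chr1", c(100, 101, 300),
                       meth = c(12, 8, 25), unmeth = c(8, 12, 5),
                       strand = c("+", "-", "+")))
    se <- methylationCallsFromTables(tabs, sheet, minCoverage = 10,
                                     mergeStrands = TRUE)
    expect_equal(nrow(se), 2)
    m <- SummarizedExperiment::assay(se, "meth")
    gr <- SummarizedExperiment::rowRanges(se)
    i <- which(GenomicRanges::start(gr) == 100)
    expect_equal(unname(m[i, "A1"]), 16)  # 10 + 6 summed
})

test_that("differential methylation matches the Fisher oracle and flips", {
    sheet <- twoGroupSheet(1, 1)
    tabs <- list(A1 = methTable("chr1", c(100, 200),
                                meth = c(5, 30), unmeth = c(95, 70)),
                 B1 = methTable("chr1", c(100, 200),
                                meth = c(60, 30), unmeth = c(40, 70)))
    se <- methylationCallsFromTables(tabs, sheet, minCoverage = 10)
    ds <- diffMethylation(se, "A1", "B1", returnAll = TRUE)
    i <- which(ds$pos == 100)
    expect_equal(ds$meth_diff[i], 55)
    expect_equal(ds$direction[i], "up")
    expect_equal(ds$p_value[i], oracleFisher(5, 95, 60, 40),
                 tolerance = 1e-12)
    # identical pooled rates: difference 0, never called
    j <- which(ds$pos == 200)
    expect_equal(ds$meth_diff[j], 0)
    expect_false(ds$significant[j])
    # antisymmetry: swapped groups flip the difference, keep q
    sw <- diffMethylation(se, "B1", "A1", returnAll = TRUE)
    expect_equal(sw$meth_diff, -ds$meth_diff)
    expect_equal(sw$q_value, ds$q_value)
    expect_equal(sw$direction[i], "down")
})

test_that("stricter thresholds never enlarge the differential set", {
    set.seed(101)
    sheet <- twoGroupSheet(3, 3)
    n <- 300
    tabs <- lapply(1:6, function(i) {
        cov <- rpois(n, 40)
        meth <- rbinom(n, cov, rbeta(n, 4, 12))
        methTable("chr1", seq_len(n) * 50, meth, cov - meth)
    })
    names(tabs) <- sheet$sample_id
    se <- methylationCallsFromTables(tabs, sheet)
    n1 <- nrow(diffMethylation(se, sheet$sample_id[1:3],
                               sheet$sample_id[4:6],
                               diffMin = 10, qMax = 0.05))
    n2 <- nrow(diffMethylation(se, sheet$sample_id[1:3],
                               sheet$sample_id[4:6],
                               diffMin = 25, qMax = 0.05))
    n3 <- nrow(diffMethylation(se, sheet$sample_id[1:3],
                               sheet$sample_id[4:6],
                               diffMin = 25, qMax = 0.01))
    expect_true(n1 >= n2 && n2 >= n3)
})

test_that("the Fisher/BH stage holds the FDR on overdispersed nulls", {
    set.seed(111)
    sheet <- twoGroupSheet(3, 3)
    fracs <- replicate(25, {
        n <- 2000
        level <- rbeta(n, 4, 16)
        tabs <- lapply(1:6, function(i) {
            cov <- rpois(n, 30)
            q <- rbeta(n, level * 50, (1 - level) * 50)
            meth <- rbinom(n, cov, q)
            methTable("chr1", seq_len(n) * 50, meth, cov - meth)
        })
        names(tabs) <- sheet$sample_id
        se <- methylationCallsFromTables(tabs, sheet)
        ds <- diffMethylation(se, sheet$sample_id[1:3],
                              sheet$sample_id[4:6], diffMin = 0,
                              qMax = 0.01)
        nrow(ds) / nrow(se)
    })
    expect_lte(mean(fracs), 0.01)
})

test_that("DMSG records carry location, function and site multiplicity", {
    sc <- table1Scenario()
    dmsg <- buildDmsgs(sc$sites, sc$catalog, sc$functional)
    expect_equal(nrow(dmsg), 22)
    byPath <- table(sc$functional$pathway[match(unique(dmsg$gene_id),
                                                sc$functional$gene_id)])
    expect_equal(unname(byPath["ion"]), 14)
    expect_equal(unname(byPath["faa"]), 8)
    expect_equal(tolower(dmsg$location[match(sc$table$gene_id,
                                             dmsg$gene_id)]),
                 gsub(" ", "_", tolower(sc$table$location)))
    # an intergenic site contributes nothing
    far <- data.frame(chrom = "chrZ", pos = 10, meth_diff = 40,
                      direction = "up", stringsAsFactors = FALSE)
    expect_equal(nrow(buildDmsgs(far, sc$catalog, sc$functional)), 0)
})

test_that("a site shared by two genes yields two DMSG records", {
    genes <- data.frame(
        chrom = "chr1", start = c(10000, 13500), end = c(13000, 16000),
        strand = "+", id = c("gA", "gB"), l5 = 100, lc = 2000,
        l3 = c(901, 401), name = c("A", "B"), stringsAsFactors = FALSE)
    cat6 <- toyCatalog(genes)
    site <- data.frame(chrom = "chr1", pos = 12000, meth_diff = 30,
                       direction = "up", stringsAsFactors = FALSE)
    dmsg <- buildDmsgs(site, cat6)
    expect_equal(nrow(dmsg), 2)
    expect_setequal(dmsg$location, c("gene_body", "promoter"))
})

test_that("gene methylation level is the unweighted site mean", {
    sheet <- twoGroupSheet(1, 1)
    genes <- data.frame(chrom = "chr1", start = 5000, end = 8000,
                        strand = "+", id = "g1", l5 = 200, lc = 2000,
                        l3 = 801, name = NA_character_,
                        stringsAsFactors = FALSE)
    cat7 <- toyCatalog(genes)
    pos <- c(5100, 5500, 6000, 6500, 7000)
    meth <- c(10, 0, 20, 5, 15)
    unmeth <- c(10, 20, 0, 15, 5)
    tabs <- list(A1 = methTable("chr1", pos, meth, unmeth),
                 B1 = methTable("chr1", pos, meth, unmeth))
    se <- methylationCallsFromTables(tabs, sheet)
    lv <- geneMethylationLevels(se, cat7)
    hand <- mean(meth / (meth + unmeth))
    expect_equal(unname(lv["g1"]), hand)
    # single site at 50/50 and the two-site 1.0/0.0 average
    tabs2 <- list(A1 = methTable("chr1", 6000, 25, 25),
                  B1 = methTable("chr1", 6000, 25, 25))
    se2 <- methylationCallsFromTables(tabs2, sheet)
    expect_equal(unname(geneMethylationLevels(se2, cat7)["g1"]), 0.5)
    expect_equal(unname(geneSiteCounts(se, cat7)["g1"]), 5L)
})

test_that("methylation-expression direction follows the profile shapes", {
    prof <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.6)
    expr <- c(10, 30, 20, 50, 40, 60)
    expect_equal(methylationExpressionDirection(prof, expr), "positive")
    expect_equal(methylationExpressionDirection(prof, -expr), "negative")
    expect_error(methylationExpressionDirection(rep(0.2, 6), expr),
                 "variance")
})

test_that("planted negative methylation-expression coupling is recovered", {
    # beta-binomial methylation whose level tracks the mirrored
    # expression profile, as the generator plants for negative coupling
    set.seed(121)
    ok <- replicate(200, {
        expr <- 100 * 2^c(0, 2, 2, 0, 2, 2) * exp(rnorm(6, 0, 0.1))
        lvl <- 0.5 - 0.15 * (expr - min(expr)) / diff(range(expr))
        cov <- rpois(6, 200)
        meth <- rbinom(6, cov, rbeta(6, lvl * 60, (1 - lvl) * 60))
        methylationExpressionDirection(meth / cov, expr) == "negative"
    })
    expect_gte(mean(ok), 0.95)
})
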