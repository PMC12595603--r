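test_that("regulation modes follow the 2x2 evidence table exactly", {
    genes <- sprintf("g%02d", 1:12)
    pairs <- data.frame(mirna_id = c("m1", "m2", "m3", "m4"),
                        gene_id = c("g01", "g02", "g02", "g03"),
                        stringsAsFactors = FALSE)
    dmsgs <- data.frame(gene_id = c("g03", "g04", "g04", "g05"),
                        stringsAsFactors = FALSE)
    degs <- sprintf("g%02d", 1:6)
    calls <- classifyRegulation(24, degs, pairs, dmsgs, genes)
    want <- c(g01 = "mirna_only", g02 = "mirna_only", g03 = "dual",
              g04 = "methylation_only", g05 = "methylation_only",
              g06 = "none")
    expect_equal(stats::setNames(calls$mode, calls$gene_id), want)
    # cohort restricted to differential functional genes
    expect_equal(nrow(calls), 6)
    # partition: exactly one mode per gene, counts add up
    expect_equal(sum(table(calls$mode)), nrow(calls))
    wide <- classifyRegulation(24, degs, pairs, dmsgs, genes,
                               cohort = "functional")
    expect_equal(nrow(wide), 12)
})

test_that("mode proportions normalise over evidence-bearing genes", {
    calls <- data.frame(
        gene_id = sprintf("g%d", 1:16),
        time_h = 24,
        mode = c(rep("mirna_only", 4), "methylation_only",
                 rep("none", 11)),
        stringsAsFactors = FALSE)
    mp <- modeProportions(calls)
    expect_equal(unname(mp$proportions), c(0.8, 0.2, 0))
    expect_equal(mp$n_none, 11)
    allDual <- data.frame(gene_id = "g", time_h = 24, mode = "dual")
    expect_equal(unname(modeProportions(allDual)$proportions),
                 c(0, 0, 1))
    none <- data.frame(gene_id = "g", time_h = 24, mode = "none")
    expect_true(all(is.na(modeProportions(none)$proportions)))
})

test_that("generator defaults reproduce miRNA-dominant regulation", {
    cfg <- simConfig(nGenes = 150, nMirnas = 25, fracFunctional = 0.8)
    ok <- vapply(1:100, function(s) {
        b <- generateBundle(cfg, seed = 200 + s)
        tm <- b$truth$modes
        tm <- tm[tm$time_h == 48 & tm$mode != "none", ]
        if (!nrow(tm)) return(NA)
        mean(tm$mode == "mirna_only") > 0.5
    }, logical(1))
    expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("permutation test honours forced and degenerate overlaps", {
    uni <- sprintf("g%02d", 1:10)
    # nA = N forces every null overlap to nB
    res <- dualRegulationPermutation(uni, uni, uni[1:3],
                                     iterations = 200, seed = 1)
    expect_true(all(nullOverlaps(res) == 3))
    expect_equal(empiricalP(res), 1)
    # zero observed overlap is never significant
    res0 <- dualRegulationPermutation(uni, uni[1:5], uni[6:9],
                                      iterations = 200, seed = 1)
    expect_equal(observedOverlap(res0), 0L)
    expect_gte(empiricalP(res0), 200 / 201)
    expect_error(dualRegulationPermutation(uni, c(uni, "gX"), uni[1:2]),
                 "subsets")
})

test_that("permutation draws are reproducible and leave the RNG alone", {
    uni <- sprintf("g%03d", 1:50)
    r1 <- dualRegulationPermutation(uni, uni[1:10], uni[5:20],
                                    iterations = 300, seed = 99)
    r2 <- dualRegulationPermutation(uni, uni[1:10], uni[5:20],
                                    iterations = 300, seed = 99)
    expect_identical(nullOverlaps(r1), nullOverlaps(r2))
    set.seed(7)
    before <- runif(1)
    set.seed(7)
    invisible(dualRegulationPermutation(uni, uni[1:10], uni[5:20],
                                        iterations = 50, seed = 3))
    expect_identical(runif(1), before)
})

test_that("the permutation null matches the hypergeometric law", {
    uni <- sprintf("g%02d", 1:20)
    res <- dualRegulationPermutation(uni, uni[1:5], uni[1:4],
                                     iterations = 10000, seed = 13)
    # mean within 3 SE of nA*nB/N
    m <- 5 * 4 / 20
    v <- 4 * (5 / 20) * (15 / 20) * (16 / 19)
    expect_lt(abs(mean(nullOverlaps(res)) - m),
              3 * sqrt(v / 10000))
    # the add-one p matches the exact tail within Monte-Carlo error
    tail <- stats::phyper(res@observedOverlap - 1, 5, 15, 4,
                          lower.tail = FALSE)
    mcSd <- sqrt(tail * (1 - tail) / 10000)
    expect_lt(abs(empiricalP(res) - tail), 3 * mcSd + 2 / 10001)
})

test_that("empirical p is super-uniform under a true null", {
    uni <- sprintf("g%03d", 1:80)
    set.seed(131)
    ps <- replicate(500, {
        a <- sample(uni, 15)
        b <- sample(uni, 10)
        empiricalP(dualRegulationPermutation(uni, a, b,
                                             iterations = 60))
    })
    for (alpha in c(0.05, 0.1, 0.25)) {
        expect_lte(mean(ps <= alpha), alpha + 0.035)
    }
})

test_that("complementarity reporting summarises groups and flips labels", {
    set.seed(141)
    lv <- matrix(rbeta(200, 4, 16), 100, 2,
                 dimnames = list(sprintf("g%03d", 1:100), c("0", "24")))
    targeted <- rownames(lv)[1:40]
    other <- rownames(lv)[41:100]
    sc <- stats::setNames(rpois(100, 3), rownames(lv))
    rep1 <- structuralComplementarity(targeted, other, lv, sc)
    expect_equal(nrow(rep1$levels), 2)
    expect_equal(rep1$levels$n_targeted, c(40, 40))
    # identical distributions: no stars expected at these sizes
    expect_true(all(rep1$levels$p > 0.001))
    # label swap keeps p, swaps the group summaries
    rep2 <- structuralComplementarity(other, targeted, lv, sc)
    expect_equal(rep2$levels$p, rep1$levels$p)
    expect_equal(rep2$levels$mean_targeted, rep1$levels$mean_other)
    expect_equal(rep2$site_counts$p, rep1$site_counts$p)
    # gene order within groups is irrelevant
    rep3 <- structuralComplementarity(rev(targeted), sample(other), lv,
                                      sc)
    expect_equal(rep3$levels$p, rep1$levels$p)
    # NA-level genes are excluded and counted
    lv2 <- lv
    lv2[1, ] <- NA
    rep4 <- structuralComplementarity(targeted, other, lv2, sc)
    expect_equal(rep4$levels$n_targeted, c(39, 39))
    expect_equal(rep4$n_missing, 2L)
})

test_that("|log2FC| group comparisons handle empty and degenerate groups", {
    calls <- data.frame(
        gene_id = c("a", "b", "c"),
        time_h = 24,
        mode = c("mirna_only", "methylation_only", "dual"),
        stringsAsFactors = FALSE)
    lfc <- c(a = 1.5, b = -2, c = 3)
    res <- lfcGroupComparison(calls, lfc)
    expect_equal(res$p, c(1, 1))  # single observations: exact p = 1
    noDual <- calls[calls$mode != "dual", ]
    res2 <- lfcGroupComparison(noDual, lfc)
    expect_true(all(is.na(res2$p)))
})

test_that("machinery watchlist hits are reported per layer", {
    pairs <- data.frame(mirna_id = "mir-4046-5p", gene_id = "gM",
                        symbol = "MBD2", region = "utr3",
                        sign = "positive", stringsAsFactors = FALSE)
    dmsgs <- data.frame(gene_id = rep("gD", 3), symbol = rep("DGCR8", 3),
                        direction = c("up", "up", "up"),
                        stringsAsFactors = FALSE)
    rep1 <- mutualRegulationReport(pairs, dmsgs)
    mi <- rep1[rep1$layer == "mirna", ]
    expect_equal(mi$symbol, "MBD2")
    expect_equal(mi$region, "utr3")
    expect_equal(mi$sign, "positive")
    me <- rep1[rep1$layer == "methylation", ]
    expect_equal(me$symbol, "DGCR8")
    expect_equal(me$site_count, 3L)
    empty <- mutualRegulationReport(pairs, dmsgs, watchlist = "XYZ")
    expect_equal(nrow(empty), 0)
})

test_that("the enrichment hook runs a one-sided hypergeometric test", {
    uni <- sprintf("g%02d", 1:40)
    tm <- data.frame(gene_id = uni[1:10], term = "osmo",
                     stringsAsFactors = FALSE)
    res <- termEnrichment(uni[1:8], uni, tm)
    expect_equal(res$n_overlap, 8)
    expect_equal(res$p,
                 stats::phyper(7, 10, 30, 8, lower.tail = FALSE))
})
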