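# Hand-coded reference implementations, independent of the package's
# wrappers, used as oracles for the dual-route statistical checks.

oraclePearson <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracleWilcoxExact <- function(a, b) {
    n1 <- length(a)
    n2 <- length(b)
    pooled <- rank(c(a, b))
    wObs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    wAll <- colSums(matrix(pooled[combos], nrow = n1)) -
        n1 * (n1 + 1) / 2
    pmfLe <- mean(wAll <= wObs)
    pmfGe <- mean(wAll >= wObs)
    if (wObs > n1 * n2 / 2) min(1, 2 * pmfGe) else min(1, 2 * pmfLe)
}

# normal approximation with tie and continuity correction, from the
# classical formulas
oracleWilcoxApprox <- function(a, b) {
    n1 <- length(a)
    n2 <- length(b)
    pooled <- rank(c(a, b))
    w <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
    z <- w - n1 * n2 / 2
    nt <- table(pooled)
    sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) -
                   sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

# step-up BH with monotonicity, written from the definition
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# two-sided Fisher exact p for a 2x2 table via the hypergeometric pmf
# (sum of outcomes no more probable than the observed one)
oracleFisher <- function(a, b, c, d) {
    m <- a + b
    n <- c + d
    k <- a + c
    support <- max(0, k - n):min(k, m)
    pmf <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(pmf[pmf <= pObs * (1 + 1e-7)])
}

# brute-force promoter/gene-body assignment by direct coordinate scan
oracleSiteLocation <- function(chrom, pos, gChrom, gStart, gEnd, gStrand,
                               upstream = 2000, chromLen = NA) {
    if (chrom != gChrom) return("none")
    if (pos >= gStart && pos <= gEnd) return("gene_body")
    if (gStrand == "+") {
        lo <- max(1, gStart - upstream)
        hi <- gStart - 1
    } else {
        lo <- gEnd + 1
        hi <- gEnd + upstream
        if (!is.na(chromLen)) hi <- min(hi, chromLen)
    }
    if (pos >= lo && pos <= hi) "promoter" else "none"
}

# per-base overlap counting for binding-region assignment
oracleBindingRegion <- function(tStart, tEnd, l5, lc, l3) {
    bases <- tStart:(tEnd - 1)
    counts <- c(utr5 = sum(bases < l5),
                cds = sum(bases >= l5 & bases < l5 + lc),
                utr3 = sum(bases >= l5 + lc))
    best <- names(counts)[counts == max(counts)]
    prio <- c(utr3 = 3, cds = 2, utr5 = 1)
    best[which.max(prio[best])]
}
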