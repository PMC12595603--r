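#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (the test behind \code{stats::cor.test}). The categorical \code{sign}
#' drives the positive/negative labelling of miRNA-target and
#' methylation-expression relations; \code{r} exactly 0 is labelled
#' \code{"zero"} and excluded from positive/negative tallies downstream.
#'
#' @param x,y numeric vectors of equal length, n >= 3, nonzero variance.
#' @return list with elements \code{r}, \code{p_value}, \code{n},
#'   \code{sign}.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    n <- length(x)
    if (n < 3) stop("need at least 3 paired observations, got ", n)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance input")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate)
    list(r = r,
         # keep p strictly positive even at |r| = 1 (t = Inf)
         p_value = max(unname(ct$p.value), .Machine$double.xmin),
         n = n,
         sign = if (r > 0) "positive" else if (r < 0) "negative" else "zero")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test. The exact null distribution is
#' used when the pooled sample is small (n1 + n2 <= \code{exactMax}) and
#' tie-free -- the regime of this design's 3-6 replicates, where the normal
#' approximation is poor -- and the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param exactMax largest pooled size for the exact distribution
#'   (default 16).
#' @return list with elements \code{statistic} (Mann-Whitney W for the
#'   first sample), \code{p_value}, \code{n1}, \code{n2}, \code{exact}.
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 16) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    ties <- anyDuplicated(c(a, b)) > 0
    useExact <- (length(a) + length(b)) <= exactMax && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = useExact,
                                              correct = TRUE,
                                              alternative = "two.sided"))
    list(statistic = unname(wt$statistic),
         p_value = min(1, unname(wt$p.value)),
         n1 = length(a), n2 = length(b), exact = useExact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output is in input order and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Significance stars at the conventional thresholds
#'
#' 0.05 / 0.01 / 0.001 / 0.0001, matching the box-plot annotation scheme
#' used for the methylation-level comparisons.
#'
#' @param p numeric vector of p-values.
#' @return character vector of "", "*", "**", "***", "****".
#' @export
significanceStars <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "")) |> as.character()
}
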