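# Group-level inference: signed-rank tests against chance, FDR control,
# and effect sizes.

#' Wilcoxon signed-rank test against a null value
#'
#' Two-tailed Wilcoxon signed-rank test of the hypothesis that the
#' per-subject statistics come from a distribution with median equal to
#' \code{nullValue} (50 for pairwise classification accuracy, 0 for
#' correlations and distances). Zero differences are dropped; the exact
#' null distribution is used for small samples without ties and a
#' continuity-corrected normal approximation otherwise (the
#' \code{stats::wilcox.test} conventions).
#'
#' @param values numeric per-subject statistics (n >= 5).
#' @param nullValue null median.
#' @return A one-row data.frame with columns \code{statistic} (V),
#'   \code{p}, \code{n} (non-zero differences), \code{z} (normal
#'   approximation of the signed-rank statistic) and \code{degenerate}
#'   (TRUE when all differences are zero).
#' @export
wilcoxonVsChance <- function(values, nullValue = 50) {
    stopifnot(length(values) >= 5L)
    d <- values - nullValue
    nz <- sum(d != 0)
    if (nz == 0L)
        return(data.frame(statistic = NA_real_, p = 1, n = 0L,
                          z = 0, degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0,
                                              alternative = "two.sided"))
    data.frame(statistic = unname(wt$statistic), p = wt$p.value,
               n = nz, z = .signedRankZ(d), degenerate = FALSE)
}

# Continuity-corrected normal statistic of the signed-rank test, with
# tie and zero handling; used for the r = Z / sqrt(N) effect size.
.signedRankZ <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (!n) return(0)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(ties^3 - ties) / 48
    if (sig2 <= 0) return(0)
    cc <- sign(V - mu) * 0.5
    (V - mu - cc) / sqrt(sig2)
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false discovery rate control at level \code{q}: hypotheses
#' with BH-adjusted p-value at most \code{q} are rejected.
#'
#' @param pValues numeric p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return A data.frame with columns \code{p}, \code{pAdjusted} and
#'   \code{significant}.
#' @export
fdrCorrect <- function(pValues, q = 0.05) {
    stopifnot(all(pValues >= 0 & pValues <= 1))
    padj <- stats::p.adjust(pValues, method = "BH")
    data.frame(p = pValues, pAdjusted = padj, significant = padj <= q)
}

#' Partial eta squared
#'
#' \code{SS_effect / (SS_effect + SS_residual)}, the proportion of the
#' effect-plus-error variance attributable to the effect in a
#' repeated-measures ANOVA.
#'
#' @param ssEffect,ssResidual sums of squares (>= 0, not both zero).
#' @return Value in [0, 1].
#' @export
partialEtaSquared <- function(ssEffect, ssResidual) {
    stopifnot(ssEffect >= 0, ssResidual >= 0)
    if (ssEffect + ssResidual == 0)
        stop("undefined effect size: both sums of squares are zero")
    ssEffect / (ssEffect + ssResidual)
}

#' Signed-rank effect size r
#'
#' \code{r = Z / sqrt(N)} for a Wilcoxon signed-rank test with normal
#' statistic \code{Z} over \code{N} subjects.
#'
#' @param z normal-approximation statistic.
#' @param n number of subjects (>= 1).
#' @return Effect size r.
#' @export
signedRankEffectSize <- function(z, n) {
    stopifnot(n >= 1)
    z / sqrt(n)
}
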