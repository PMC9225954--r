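# Subject-level bootstraps for peak latencies and searchlight peak
# distances. All resampling is seeded and bit-reproducible.

.bootResult <- function(statistic, estimate, boots, nBoot, seed,
                        p = NA_real_) {
    qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    data.frame(statistic = statistic, estimate = estimate,
               ciLow = qs[1L], ciHigh = qs[2L], p = p,
               nBoot = nBoot, seed = seed)
}

#' Bootstrap confidence interval of a group peak latency
#'
#' Resamples subjects with replacement, recomputes the group-mean time
#' course and its peak latency per resample, and reports the 2.5/97.5
#' percentile interval.
#'
#' @param subjectCourses numeric matrix, subjects x time points.
#' @param timeMs time axis in ms.
#' @param window peak search window (start, end) ms.
#' @param nBoot number of resamples (default 10000).
#' @param seed integer seed.
#' @return One-row data.frame (statistic, estimate, ciLow, ciHigh, p,
#'   nBoot, seed); \code{estimate} is the observed group peak latency,
#'   \code{p} is NA for a pure CI.
#' @export
bootstrapPeakCI <- function(subjectCourses, timeMs, window = c(0, 600),
                            nBoot = 10000, seed) {
    stopifnot(is.matrix(subjectCourses), nrow(subjectCourses) >= 2L,
              ncol(subjectCourses) == length(timeMs))
    n <- nrow(subjectCourses)
    est <- findPeakLatency(colMeans(subjectCourses), timeMs, window)
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        findPeakLatency(colMeans(subjectCourses[idx, , drop = FALSE]),
                        timeMs, window)
    }, numeric(1)))
    .bootResult("peak_latency_ms", est, boots, nBoot, seed)
}

#' Bootstrap test of a peak-latency difference
#'
#' Paired subject bootstrap of the peak-latency difference B - A between
#' two conditions: per resample the same subjects are drawn for both
#' condition matrices, group-mean courses are formed, and the peak
#' latency difference is recorded. The one-tailed p-value is the
#' proportion of resampled differences less than or equal to zero
#' (evidence that B peaks later than A when small).
#'
#' @param coursesA,coursesB numeric matrices, subjects x time points
#'   (same subjects, same order).
#' @param timeMs,window,nBoot,seed as in [bootstrapPeakCI()].
#' @return One-row data.frame; \code{estimate} is the observed group
#'   difference B - A in ms.
#' @export
bootstrapDifference <- function(coursesA, coursesB, timeMs,
                                window = c(0, 600), nBoot = 10000, seed) {
    stopifnot(identical(dim(coursesA), dim(coursesB)),
              nrow(coursesA) >= 2L)
    n <- nrow(coursesA)
    est <- findPeakLatency(colMeans(coursesB), timeMs, window) -
           findPeakLatency(colMeans(coursesA), timeMs, window)
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        findPeakLatency(colMeans(coursesB[idx, , drop = FALSE]),
                        timeMs, window) -
        findPeakLatency(colMeans(coursesA[idx, , drop = FALSE]),
                        timeMs, window)
    }, numeric(1)))
    p <- mean(boots <= 0)
    .bootResult("peak_latency_difference_ms", est, boots, nBoot, seed,
                p = p)
}

#' Label-shuffle test of a searchlight peak distance
#'
#' Tests whether the Euclidean distance between the group-mean accuracy
#' peaks of two conditions is larger than expected under exchangeable
#' condition labels. The observed statistic is the distance between the
#' peak coordinates of the two subject-mean maps (peak = maximum,
#' deterministic tie-break by voxel order). The null distribution swaps
#' the two condition maps within each subject at random and recomputes
#' the statistic; the one-tailed p-value is the proportion of null
#' distances at least as large as the observed one.
#'
#' @param mapsA,mapsB numeric matrices, subjects x voxels (same voxel
#'   order; same subjects).
#' @param coords voxels x d coordinate matrix (grid units).
#' @param nBoot number of label shuffles (default 10000).
#' @param seed integer seed.
#' @return One-row data.frame with the observed distance (grid units),
#'   the null-quantile CI columns and the one-tailed p; a \code{flat}
#'   attribute flags group maps without a unique peak.
#' @export
bootstrapSearchlightPeakDistance <- function(mapsA, mapsB, coords,
                                             nBoot = 10000, seed) {
    stopifnot(identical(dim(mapsA), dim(mapsB)),
              ncol(mapsA) == nrow(coords))
    n <- nrow(mapsA)
    peakOf <- function(m) coords[which.max(colMeans(m)), ]
    dist2 <- function(a, b) sqrt(sum((a - b)^2))
    flat <- function(m) {
        mu <- colMeans(m)
        sum(mu == max(mu)) > 1L
    }
    est <- dist2(peakOf(mapsA), peakOf(mapsB))
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
        swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
        a <- mapsA; bb <- mapsB
        a[swap, ] <- mapsB[swap, , drop = FALSE]
        bb[swap, ] <- mapsA[swap, , drop = FALSE]
        dist2(peakOf(a), peakOf(bb))
    }, numeric(1)))
    out <- .bootResult("searchlight_peak_distance", est, boots, nBoot,
                       seed, p = mean(boots >= est))
    attr(out, "flat") <- flat(mapsA) || flat(mapsB)
    out
}
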