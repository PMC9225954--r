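#' Signed peak-to-diagonal shift
#'
#' Location of the post-stimulus maximum of a temporal generalization
#' matrix and its signed perpendicular distance from the train-time =
#' test-time diagonal.
#'
#' @slot pX test-axis peak time (ms).
#' @slot pY train-axis peak time (ms).
#' @slot bX diagonal foot coordinate (ms), \code{(pX + pY) / 2}.
#' @slot dEuclidean signed distance (ms); negative iff \code{pX < pY}
#'   (peak above the diagonal).
#' @slot tied TRUE if the matrix maximum was tied and resolved by the
#'   documented tie rule.
#'
#' @seealso [peakToDiagonal()]
#' @export
setClass("PeakShift",
    representation(pX = "numeric", pY = "numeric", bX = "numeric",
                   dEuclidean = "numeric", tied = "logical"))

setMethod("show", "PeakShift", function(object) {
    cat(sprintf(
        "PeakShift: peak (test %g ms, train %g ms), foot b_x = %g ms, d = %+.2f ms%s\n",
        object@pX, object@pY, object@bX, object@dEuclidean,
        if (object@tied) " (tied maximum)" else ""))
})

#' Peak-to-diagonal distance of a generalization matrix
#'
#' Finds the maximum of the matrix within a post-stimulus search window
#' and computes the signed perpendicular Euclidean distance between the
#' peak and the diagonal: with peak coordinates \code{(pX, pY)} (test and
#' train time), the closest diagonal point is \code{bX = (pX + pY) / 2},
#' and \code{d = sqrt((pX - bX)^2 + (pY - bX)^2)}, multiplied by -1 when
#' \code{pX < pY} (peaks above the diagonal), so that positive values
#' indicate generalization to later test times. Exact ties at the
#' maximum are resolved to the entry closest to the diagonal, then to
#' the earliest train time, and flagged.
#'
#' @param matrix a [GeneralizationMatrix-class].
#' @param peakWindow (start, end) ms search window applied to both axes
#'   (default 0...600 ms, post-stimulus).
#' @return A [PeakShift-class].
#' @examples
#' m <- matrix(50, 3, 3)
#' m[2, 3] <- 90  # train 100 ms, test 300 ms
#' gm <- new("GeneralizationMatrix", accuracy = m,
#'           trainAxisMs = c(0, 100, 300), testAxisMs = c(0, 100, 300),
#'           trainCondition = "no", testCondition = "high",
#'           target = "location")
#' peakToDiagonal(gm)  # d = +141.42 ms
#' @export
peakToDiagonal <- function(matrix, peakWindow = c(0, 600)) {
    stopifnot(is(matrix, "GeneralizationMatrix"))
    ri <- which(matrix@trainAxisMs >= peakWindow[1L] &
                matrix@trainAxisMs <= peakWindow[2L])
    ci <- which(matrix@testAxisMs >= peakWindow[1L] &
                matrix@testAxisMs <= peakWindow[2L])
    if (!length(ri) || !length(ci))
        stop("peak window does not intersect the matrix axes")
    sub <- matrix@accuracy[ri, ci, drop = FALSE]
    mx <- max(sub)
    hits <- which(sub == mx, arr.ind = TRUE)
    tied <- nrow(hits) > 1L
    pys <- matrix@trainAxisMs[ri[hits[, 1L]]]
    pxs <- matrix@testAxisMs[ci[hits[, 2L]]]
    ord <- order(abs(pxs - pys), pys, pxs)
    pX <- pxs[ord[1L]]; pY <- pys[ord[1L]]
    bX <- (pX + pY) / 2
    d <- sqrt((pX - bX)^2 + (pY - bX)^2)
    if (pX < pY) d <- d * -1
    new("PeakShift", pX = pX, pY = pY, bX = bX, dEuclidean = d,
        tied = tied)
}

#' Diagonal difference of a generalization matrix
#'
#' Subtracts each entry's mirror across the diagonal from the entry
#' itself: \code{out[i, j] = acc[i, j] - acc[j, i]}. Entries below the
#' diagonal therefore carry "below minus above" accuracy differences,
#' the diagonal is zero, and the output is exactly antisymmetric.
#'
#' @param matrix a square [GeneralizationMatrix-class] (equal axes).
#' @return Numeric antisymmetric matrix with the same dimnames.
#' @export
diagonalDifference <- function(matrix) {
    stopifnot(is(matrix, "GeneralizationMatrix"))
    a <- matrix@accuracy
    if (nrow(a) != ncol(a))
        stop("diagonal difference requires a square matrix")
    a - t(a)
}

#' Peak latency of an accuracy time course
#'
#' Time of the maximum within a window; exact ties are broken to the
#' earliest time point. For monotone courses the window edge is
#' returned.
#'
#' @param accuracy numeric accuracy vector (or a
#'   [DecodingResult-class]).
#' @param timeMs time axis in ms (taken from the result if omitted).
#' @param window (start, end) ms search window.
#' @return Peak time in ms.
#' @export
findPeakLatency <- function(accuracy, timeMs = NULL, window = c(0, 600)) {
    if (is(accuracy, "DecodingResult")) {
        timeMs <- as.numeric(accuracy@index)
        accuracy <- accuracy@accuracy
    }
    stopifnot(length(accuracy) == length(timeMs))
    sel <- which(timeMs >= window[1L] & timeMs <= window[2L])
    if (!length(sel)) stop("empty peak search window")
    timeMs[sel[which.max(accuracy[sel])]]
}
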