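#' Down-sample a time axis by bin means
#'
#' Averages consecutive non-overlapping bins of \code{stepMs} width; the
#' new axis is labelled by bin centers. A trailing incomplete bin is
#' dropped. Bin means (rather than decimation) are used for noise
#' robustness.
#'
#' @param x an [EEGEpochSet-class], a [DecodingResult-class] time course,
#'   or a numeric vector/matrix (time along the vector / columns) with
#'   \code{timeMs} supplied.
#' @param stepMs new resolution in ms; must be a multiple of the native
#'   resolution.
#' @param timeMs native time axis (only for plain vectors/matrices).
#' @return Object of the same kind on the coarser axis; for plain input,
#'   a list with \code{values} and \code{timeMs}.
#' @export
downsampleTime <- function(x, stepMs, timeMs = NULL) {
    if (is(x, "EEGEpochSet")) {
        b <- .dsBins(x@timeMs, stepMs)
        d <- dim(x@data)
        nb <- length(b$centers)
        out <- array(0, c(d[1L], d[2L], nb))
        for (i in seq_len(nb)) {
            idx <- b$keep[b$groups == i]
            out[, , i] <- matrix(
                rowMeans(array(x@data[, , idx, drop = FALSE],
                               c(d[1L] * d[2L], b$n)), dims = 1L),
                d[1L], d[2L])
        }
        return(new("EEGEpochSet", data = out, labels = x@labels,
                   timeMs = b$centers, layout = x@layout,
                   design = x@design))
    }
    if (is(x, "DecodingResult")) {
        b <- .dsBins(as.numeric(x@index), stepMs)
        acc <- as.vector(tapply(x@accuracy[b$keep], b$groups, mean))
        cells <- rowsum(x@cellAccuracy[b$keep, , drop = FALSE],
                        b$groups) / b$n
        names(acc) <- b$centers
        return(new("DecodingResult", accuracy = acc, index = b$centers,
                   cellAccuracy = cells, cellIndex = x@cellIndex,
                   target = x@target, clutter = x@clutter,
                   nCellsAveraged = x@nCellsAveraged, chance = x@chance))
    }
    if (is.null(timeMs)) stop("'timeMs' is required for plain input")
    b <- .dsBins(timeMs, stepMs)
    if (is.matrix(x)) {
        v <- t(rowsum(t(x[, b$keep, drop = FALSE]), b$groups) / b$n)
        colnames(v) <- b$centers
    } else {
        v <- as.vector(tapply(x[b$keep], b$groups, mean))
        names(v) <- b$centers
    }
    list(values = v, timeMs = b$centers)
}

.dsBins <- function(timeMs, stepMs) {
    native <- if (length(timeMs) > 1L) timeMs[2L] - timeMs[1L] else stepMs
    n <- stepMs / native
    if (n < 1 - 1e-9)
        stop("step (", stepMs, " ms) smaller than native resolution (",
             native, " ms)")
    if (abs(n - round(n)) > 1e-6)
        stop("step must be a multiple of the native resolution")
    n <- as.integer(round(n))
    nb <- length(timeMs) %/% n
    if (nb < 1L) stop("time axis shorter than one bin")
    keep <- seq_len(nb * n)
    groups <- rep(seq_len(nb), each = n)
    centers <- as.vector(tapply(timeMs[keep], groups, mean))
    # groups aligned with the full axis for tensor subsetting
    fullGroups <- rep(NA_integer_, length(timeMs))
    fullGroups[keep] <- groups
    list(n = n, keep = keep, groups = fullGroups[keep],
         centers = centers)
}

#' Temporal generalization across background conditions
#'
#' Trains the pairwise cross-decoding scheme at every time point of the
#' training epoch set and tests it at every time point of the testing
#' epoch set (typically: train on the no-clutter, test on the
#' high-clutter condition), on a uniform grid of \code{stepMs} steps over
#' \code{window}. As in [crossDecodeTimecourse()], training uses
#' \code{nBins - 1} pseudo-trials per class and testing one pseudo-trial,
#' and every matrix entry averages the full scheme across
#' \code{nIterations} random assignments (7,200 cells under defaults).
#' Grid points are the native samples closest to the requested grid; the
#' native resolution must be at least as fine as \code{stepMs}.
#'
#' @param epochsTrain,epochsTest [EEGEpochSet-class] objects sharing
#'   channel space and time axis (e.g. two clutter conditions from
#'   [subsetEpochs()]).
#' @param target factor to decode.
#' @param scheme a [PairScheme-class]; default: full scheme of the
#'   training set's design.
#' @param window (start, end) ms of the peri-stimulus grid.
#' @param stepMs grid step in ms.
#' @param nBins,nIterations,seed,cost as in [crossDecodeTimecourse()].
#' @return A [GeneralizationMatrix-class] (train time x test time).
#' @export
temporalGeneralization <- function(epochsTrain, epochsTest,
                                   target = c("location", "category"),
                                   scheme = NULL, window = c(-100, 600),
                                   stepMs = 10, nBins = 4,
                                   nIterations = 100, seed, cost = 1) {
    target <- match.arg(target)
    validObject(epochsTrain); validObject(epochsTest)
    if (!isTRUE(all.equal(epochsTrain@timeMs, epochsTest@timeMs)) ||
        dim(epochsTrain@data)[2L] != dim(epochsTest@data)[2L])
        stop("train and test sets must share channel space and time axis")
    timeMs <- epochsTrain@timeMs
    if (window[1L] < timeMs[1L] - 1e-9 ||
        window[2L] > timeMs[length(timeMs)] + 1e-9)
        stop("window outside the epoch range")
    native <- timeMs[2L] - timeMs[1L]
    if (stepMs < native - 1e-9)
        stop("stepMs finer than the native resolution")
    gridMs <- seq(window[1L], window[2L], by = stepMs)
    slices <- vapply(gridMs, function(g) which.min(abs(timeMs - g)),
                     integer(1))
    gridMs <- timeMs[slices]
    if (is.null(scheme)) scheme <- buildPairScheme(epochsTrain@design)
    roles <- .schemeRoles(scheme, target)

    prep <- function(ep) {
        d <- dim(ep@data)
        mat <- matrix(ep@data[, , slices, drop = FALSE],
                      d[1L], d[2L] * length(slices))
        g <- .trialGroups(ep@labels, roles)
        .checkCells(g, roles)
        list(mat = mat, groups = g, nCh = d[2L])
    }
    trn <- prep(epochsTrain)
    tst <- prep(epochsTest)
    nG <- length(slices)
    nBins <- as.integer(nBins)
    clutTrain <- unique(epochsTrain@labels$clutter)
    clutTest <- unique(epochsTest@labels$clutter)

    acc <- withSeed(seed, {
        acc <- matrix(0, nG, nG)
        for (it in seq_len(nIterations)) {
            PTr <- .binGroups(trn$mat, trn$groups, nBins, trn$nCh, nG)
            PTe <- .binGroups(tst$mat, tst$groups, nBins, tst$nCh, nG)
            for (ti in seq_len(nG)) {
                cellAcc <- .decodeCellsAtSlice(PTr, PTe, roles, nBins,
                                               ti, seq_len(nG), cost)
                acc[ti, ] <- acc[ti, ] + colMeans(cellAcc)
            }
        }
        acc / nIterations
    })
    dimnames(acc) <- list(train = gridMs, test = gridMs)
    new("GeneralizationMatrix", accuracy = acc, trainAxisMs = gridMs,
        testAxisMs = gridMs,
        trainCondition = paste(clutTrain, collapse = "+"),
        testCondition = paste(clutTest, collapse = "+"),
        target = target)
}
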