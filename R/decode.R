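# Cross-decoding engines. A "cell" is one binary classification: one
# unordered pair of class levels (the decoded factor) crossed with one
# ordered (train, test) pair of transfer-factor levels. Training data come
# exclusively from the train level and testing data from the test level of
# the transfer factor, so above-chance accuracy indicates representations
# tolerant to that factor.

.bothDirections <- function(pairs) {
    out <- matrix(character(0), 0L, 2L)
    for (i in seq_len(nrow(pairs)))
        out <- rbind(out, pairs[i, ], rev(pairs[i, ]))
    colnames(out) <- c("train", "test")
    out
}

.unorderedFromOrdered <- function(ordered) {
    ordered[seq(1L, nrow(ordered), by = 2L), , drop = FALSE]
}

# Map a PairScheme onto decoded-class and transfer roles for a target.
.schemeRoles <- function(scheme, target) {
    validObject(scheme)
    if (target == "location") {
        list(classFactor = "location", transferFactor = "category",
             classPairs = scheme@locationPairs,
             transferPairs = scheme@categoryTrainTestPairs)
    } else if (target == "category") {
        list(classFactor = "category", transferFactor = "location",
             classPairs = .unorderedFromOrdered(
                 scheme@categoryTrainTestPairs),
             transferPairs = .bothDirections(scheme@locationPairs))
    } else stop("'target' must be 'location' or 'category'")
}

# Canonical cell order: class pairs slowest, then ordered transfer pairs.
.cellIndex <- function(roles) {
    cp <- roles$classPairs; tp <- roles$transferPairs
    data.frame(
        classA = rep(cp[, 1L], each = nrow(tp)),
        classB = rep(cp[, 2L], each = nrow(tp)),
        train = rep(tp[, 1L], times = nrow(cp)),
        test = rep(tp[, 2L], times = nrow(cp)),
        stringsAsFactors = FALSE)
}

# Core cell loop on binned pseudo-trials. `PTrain` / `PTest` are nested
# lists P[[transferLevel]][[classLevel]] of nBins x nFeature x nSlice
# arrays; training uses bins 1..nBins-1 of PTrain at slice `trainSlice`,
# testing bin nBins of PTest at every slice in `testSlices` (so no raw
# trial can contribute to both sides when PTrain and PTest share a
# binning). Returns cells x length(testSlices) accuracies (percent).
.decodeCellsAtSlice <- function(PTrain, PTest, roles, nBins, trainSlice,
                                testSlices, cost = 1) {
    cp <- roles$classPairs; tp <- roles$transferPairs
    nCells <- nrow(cp) * nrow(tp)
    acc <- matrix(NA_real_, nCells, length(testSlices))
    trainBins <- seq_len(nBins - 1L)
    yTrain <- rep(c("A", "B"), each = nBins - 1L)
    for (i in seq_len(nrow(cp))) {
        a <- cp[i, 1L]; b <- cp[i, 2L]
        for (trainLvl in unique(tp[, 1L])) {
            rows <- which(tp[, 1L] == trainLvl)
            trainX <- rbind(
                PTrain[[trainLvl]][[a]][trainBins, , trainSlice, drop = FALSE][, , 1L],
                PTrain[[trainLvl]][[b]][trainBins, , trainSlice, drop = FALSE][, , 1L])
            model <- .fitLinearSVM(trainX, yTrain, cost = cost)
            for (r in rows) {
                testLvl <- tp[r, 2L]
                cellId <- (i - 1L) * nrow(tp) + r
                for (si in seq_along(testSlices)) {
                    s <- testSlices[si]
                    testX <- rbind(
                        PTest[[testLvl]][[a]][nBins, , s],
                        PTest[[testLvl]][[b]][nBins, , s])
                    pred <- .svmPredict(model, testX)
                    acc[cellId, si] <- mean(pred == c("A", "B")) * 100
                }
            }
        }
    }
    acc
}

# Bin the trials of every (transferLevel, classLevel) group of a
# trials x features x slices tensor into nBins pseudo-trials.
# Returns P[[transferLevel]][[classLevel]] = nBins x features x slices.
.binGroups <- function(dataMat, groups, nBins, nFeat, nSlice) {
    P <- list()
    for (tl in names(groups)) {
        P[[tl]] <- list()
        for (clv in names(groups[[tl]])) {
            idx <- groups[[tl]][[clv]]
            m <- length(idx)
            if (m < nBins)
                stop("infeasible binning: ", m, " trials for ", nBins,
                     " bins in cell (", tl, ", ", clv, ")")
            bins <- sample(rep_len(seq_len(nBins), m))
            sums <- rowsum(dataMat[idx, , drop = FALSE], bins,
                           reorder = TRUE)
            cnt <- tabulate(bins, nBins)
            P[[tl]][[clv]] <- array(sums / cnt, c(nBins, nFeat, nSlice))
        }
    }
    P
}

.trialGroups <- function(labels, roles) {
    groups <- list()
    for (tl in unique(labels[[roles$transferFactor]])) {
        groups[[tl]] <- list()
        for (clv in unique(labels[[roles$classFactor]]))
            groups[[tl]][[clv]] <-
                which(labels[[roles$transferFactor]] == tl &
                      labels[[roles$classFactor]] == clv)
    }
    groups
}

.checkCells <- function(groups, roles) {
    need <- unique(c(roles$transferPairs))
    for (tl in need) for (clv in unique(c(roles$classPairs)))
        if (is.null(groups[[tl]][[clv]]) || !length(groups[[tl]][[clv]]))
            stop("incomplete design: no trials for (",
                 tl, ", ", clv, ")")
}

#' Time-resolved cross-decoding of EEG epochs
#'
#' For every time point, classifies the target factor pairwise with a
#' linear SVM while training and testing on different levels of the other
#' factor. Raw trials of each condition are randomly averaged into
#' \code{nBins} pseudo-trials; the classifier is trained on
#' \code{nBins - 1} pseudo-trials per class and tested on the remaining
#' one, and the whole procedure is repeated \code{nIterations} times with
#' fresh random assignments. Accuracies are averaged over all scheme
#' cells and iterations (6 location pairs x 12 category train/test pairs
#' x 100 iterations = 7,200 cells under the defaults).
#'
#' @param epochs an [EEGEpochSet-class] (already noise-normalized if
#'   desired).
#' @param target factor to decode: \code{"location"} or
#'   \code{"category"}.
#' @param clutter clutter level to analyse.
#' @param scheme a [PairScheme-class]; default: full scheme of the
#'   epoch set's design.
#' @param nBins pseudo-trial bins per condition (default 4).
#' @param nIterations random-assignment iterations (default 100).
#' @param seed integer seed.
#' @param cost SVM regularization constant.
#' @return A [DecodingResult-class] with one accuracy per time point.
#' @export
crossDecodeTimecourse <- function(epochs, target = c("location", "category"),
                                  clutter, scheme = NULL, nBins = 4,
                                  nIterations = 100, seed, cost = 1) {
    target <- match.arg(target)
    validObject(epochs)
    if (is.null(scheme)) scheme <- buildPairScheme(epochs@design)
    roles <- .schemeRoles(scheme, target)
    ep <- subsetEpochs(epochs, clutter = clutter)
    d <- dim(ep@data)
    nTrials <- d[1L]; nCh <- d[2L]; nT <- d[3L]
    dataMat <- matrix(ep@data, nTrials, nCh * nT)
    groups <- .trialGroups(ep@labels, roles)
    .checkCells(groups, roles)
    cells <- .cellIndex(roles)
    nCells <- nrow(cells)
    nBins <- as.integer(nBins)

    cellAcc <- withSeed(seed, {
        cellAcc <- matrix(0, nT, nCells)
        for (it in seq_len(nIterations)) {
            P <- .binGroups(dataMat, groups, nBins, nCh, nT)
            for (t in seq_len(nT)) {
                cellAcc[t, ] <- cellAcc[t, ] +
                    .decodeCellsAtSlice(P, P, roles, nBins, t, t,
                                        cost)[, 1L]
            }
        }
        cellAcc / nIterations
    })

    acc <- rowMeans(cellAcc)
    names(acc) <- ep@timeMs
    new("DecodingResult", accuracy = acc, index = ep@timeMs,
        cellAccuracy = cellAcc, cellIndex = cells, target = target,
        clutter = clutter,
        nCellsAveraged = as.integer(nCells * nIterations), chance = 50)
}

#' ROI-based cross-decoding of fMRI patterns
#'
#' Randomly bins the runs into \code{nBins} pseudo-runs (averaged), then
#' performs leave-one-pseudo-run-out cross-validation: per fold, the SVM
#' is trained on the remaining pseudo-runs for a pair of target levels
#' within one level of the transfer factor and tested on the held-out
#' pseudo-run for the same pair in a different transfer level. With 10
#' runs, 5 pseudo-runs and the default scheme this averages 6 x 12 x 5 =
#' 360 accuracies.
#'
#' @param patterns an [FMRIPatternSet-class].
#' @param roi ROI name (ignored when \code{voxels} is given).
#' @param target \code{"location"} or \code{"category"}.
#' @param clutter clutter level to analyse.
#' @param scheme a [PairScheme-class]; default: full scheme of the
#'   design implied by the condition labels.
#' @param nBins number of pseudo-runs (default 5).
#' @param seed integer seed.
#' @param voxels optional explicit voxel indices (used by the
#'   searchlight).
#' @param cost SVM regularization constant.
#' @return A [DecodingResult-class] with a single accuracy.
#' @export
crossDecodeROI <- function(patterns, roi = NULL,
                           target = c("location", "category"), clutter,
                           scheme = NULL, nBins = 5, seed, voxels = NULL,
                           cost = 1) {
    target <- match.arg(target)
    validObject(patterns)
    if (is.null(voxels)) {
        if (is.null(roi)) stop("give either 'roi' or 'voxels'")
        voxels <- which(patterns@roiLabels == roi)
        if (!length(voxels)) stop("ROI not present: ", roi)
    }
    if (is.null(scheme))
        scheme <- buildPairScheme(.designFromConditions(patterns))
    roles <- .schemeRoles(scheme, target)
    condSel <- which(patterns@conditionLabels$clutter == clutter)
    if (!length(condSel)) stop("clutter level not present: ", clutter)
    labs <- patterns@conditionLabels[condSel, , drop = FALSE]
    nRuns <- dim(patterns@data)[1L]
    nBins <- as.integer(nBins)
    if (nRuns < nBins)
        stop("infeasible binning: ", nRuns, " runs for ", nBins, " bins")
    nVox <- length(voxels)
    nCond <- length(condSel)
    # runs x conditions x voxels -> runs x (cond * vox)
    dataMat <- matrix(patterns@data[, condSel, voxels, drop = FALSE],
                      nRuns, nCond * nVox)
    cells <- .cellIndex(roles)
    nCells <- nrow(cells)
    cp <- roles$classPairs; tp <- roles$transferPairs

    cellAcc <- withSeed(seed, {
        bins <- sample(rep_len(seq_len(nBins), nRuns))
        sums <- rowsum(dataMat, bins, reorder = TRUE)
        PR <- array(sums / tabulate(bins, nBins), c(nBins, nCond, nVox))
        condOf <- function(tl, clv)
            which(labs[[roles$transferFactor]] == tl &
                  labs[[roles$classFactor]] == clv)
        for (tl in unique(c(tp))) for (clv in unique(c(cp)))
            if (!length(condOf(tl, clv)))
                stop("incomplete design: missing condition (", tl, ", ",
                     clv, ")")
        cellAcc <- matrix(0, 1L, nCells)
        for (fold in seq_len(nBins)) {
            trainBins <- setdiff(seq_len(nBins), fold)
            yTrain <- rep(c("A", "B"), each = length(trainBins))
            for (i in seq_len(nrow(cp))) {
                a <- cp[i, 1L]; b <- cp[i, 2L]
                for (trainLvl in unique(tp[, 1L])) {
                    trainX <- rbind(
                        PR[trainBins, condOf(trainLvl, a), , drop = FALSE][, 1L, ],
                        PR[trainBins, condOf(trainLvl, b), , drop = FALSE][, 1L, ])
                    model <- .fitLinearSVM(trainX, yTrain, cost = cost)
                    for (r in which(tp[, 1L] == trainLvl)) {
                        testLvl <- tp[r, 2L]
                        testX <- rbind(
                            PR[fold, condOf(testLvl, a), ],
                            PR[fold, condOf(testLvl, b), ])
                        pred <- .svmPredict(model, testX)
                        cellId <- (i - 1L) * nrow(tp) + r
                        cellAcc[1L, cellId] <- cellAcc[1L, cellId] +
                            mean(pred == c("A", "B")) * 100
                    }
                }
            }
        }
        cellAcc / nBins
    })

    acc <- mean(cellAcc)
    names(acc) <- if (is.null(roi)) "voxelset" else roi
    new("DecodingResult", accuracy = acc, index = names(acc),
        cellAccuracy = cellAcc, cellIndex = cells, target = target,
        clutter = clutter, nCellsAveraged = as.integer(nCells * nBins),
        chance = 50)
}

# Recover a minimal DesignSpec from condition labels (canonical order).
.designFromConditions <- function(patterns) {
    labs <- patterns@conditionLabels
    designSpec(categories = unique(labs$category),
               exemplarsPerCategory = 1,
               locations = unique(labs$location),
               locationOffsets = .defaultOffsetsFor(unique(labs$location)),
               clutterLevels = unique(labs$clutter),
               nRuns = dim(patterns@data)[1L],
               trialsPerConditionPerRun = 1)
}

.defaultOffsetsFor <- function(locations) {
    def <- rbind("left-up" = c(-3, 3), "left-bottom" = c(-3, -3),
                 "right-up" = c(3, 3), "right-bottom" = c(3, -3))
    if (all(locations %in% rownames(def)))
        def[locations, , drop = FALSE]
    else
        cbind(seq_along(locations), seq_along(locations))
}

#' Layer-wise cross-decoding of feature activations
#'
#' Applies the time-resolved pseudo-trial scheme of
#' [crossDecodeTimecourse()] to each layer of a
#' [FeatureActivationSet-class], yielding one averaged accuracy per
#' layer.
#'
#' @inheritParams crossDecodeTimecourse
#' @param features a [FeatureActivationSet-class].
#' @return A [DecodingResult-class] indexed by layer name.
#' @export
crossDecodeFeatures <- function(features, target = c("location", "category"),
                                clutter, scheme = NULL, nBins = 4,
                                nIterations = 100, seed, cost = 1) {
    target <- match.arg(target)
    validObject(features)
    if (is.null(scheme)) {
        labs <- features@labels
        scheme <- buildPairScheme(designSpec(
            categories = unique(labs$category),
            exemplarsPerCategory = 1,
            locations = unique(labs$location),
            locationOffsets = .defaultOffsetsFor(unique(labs$location)),
            clutterLevels = unique(labs$clutter),
            nRuns = 1, trialsPerConditionPerRun = 1))
    }
    roles <- .schemeRoles(scheme, target)
    keep <- which(features@labels$clutter == clutter)
    if (!length(keep)) stop("clutter level not present: ", clutter)
    labs <- features@labels[keep, , drop = FALSE]
    groups <- .trialGroups(labs, roles)
    .checkCells(groups, roles)
    cells <- .cellIndex(roles)
    nCells <- nrow(cells)
    nBins <- as.integer(nBins)
    nLayers <- length(features@layerNames)

    cellAcc <- withSeed(seed, {
        cellAcc <- matrix(0, nLayers, nCells)
        for (li in seq_len(nLayers)) {
            X <- features@data[[features@layerNames[li]]][keep, ,
                                                          drop = FALSE]
            for (it in seq_len(nIterations)) {
                P <- .binGroups(X, groups, nBins, ncol(X), 1L)
                cellAcc[li, ] <- cellAcc[li, ] +
                    .decodeCellsAtSlice(P, P, roles, nBins, 1L, 1L,
                                        cost)[, 1L]
            }
        }
        cellAcc / nIterations
    })

    acc <- rowMeans(cellAcc)
    names(acc) <- features@layerNames
    new("DecodingResult", accuracy = acc, index = features@layerNames,
        cellAccuracy = cellAcc, cellIndex = cells, target = target,
        clutter = clutter,
        nCellsAveraged = as.integer(nCells * nIterations), chance = 50)
}

#' Select the k most activated voxels
#'
#' Returns the indices of the \code{k} largest statistic values inside a
#' mask (e.g. the 325 most activated localizer voxels within an
#' anatomical ROI mask). Ties are broken deterministically by ascending
#' grid/linear coordinate.
#'
#' @param statisticMap numeric vector or array of voxel statistics.
#' @param mask logical vector or array of the same length/shape.
#' @param k number of voxels to select (\code{k <=} masked voxel count).
#' @return Integer vector of \code{k} linear voxel indices, ordered by
#'   decreasing statistic (ties by ascending index).
#' @export
selectTopKVoxels <- function(statisticMap, mask, k) {
    stat <- as.vector(statisticMap)
    msk <- as.vector(mask)
    stopifnot(length(stat) == length(msk))
    inMask <- which(msk)
    if (!length(inMask)) stop("mask is empty")
    if (k > length(inMask))
        stop("infeasible selection: k = ", k, " exceeds ",
             length(inMask), " masked voxels")
    ord <- inMask[order(-stat[inMask], inMask)]
    ord[seq_len(k)]
}
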