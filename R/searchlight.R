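#' Integer lattice offsets of a voxel sphere
#'
#' All integer offsets \code{(dx, dy, dz)} with
#' \code{dx^2 + dy^2 + dz^2 <= radius^2}. A radius-4 sphere contains 257
#' lattice points. Distances are measured in voxel units on the grid.
#'
#' @param radius sphere radius in voxels (>= 0).
#' @return Integer matrix, offsets x 3.
#' @examples
#' nrow(sphereOffsets(4))  # 257
#' @export
sphereOffsets <- function(radius) {
    stopifnot(radius >= 0)
    r <- floor(radius)
    g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Volumetric searchlight cross-decoding
#'
#' Repeats the ROI cross-decoding analysis of [crossDecodeROI()] inside a
#' sphere of \code{radius} voxels centred on every voxel of the pattern
#' set, storing the averaged accuracy at the centre voxel. The sphere is
#' intersected with the available (in-mask) voxels; the run-to-pseudo-run
#' binning is fixed once per call (per subject and seed) and shared
#' across spheres.
#'
#' @inheritParams crossDecodeROI
#' @param radius sphere radius in voxel units (default 4).
#' @param centers optional indices of centre voxels to compute (default
#'   all).
#' @return A [SearchlightVolume-class].
#' @export
searchlightVolume <- function(patterns, target = c("location", "category"),
                              clutter, scheme = NULL, radius = 4,
                              nBins = 5, seed, centers = NULL, cost = 1) {
    target <- match.arg(target)
    validObject(patterns)
    if (is.null(scheme))
        scheme <- buildPairScheme(.designFromConditions(patterns))
    coords <- patterns@voxelCoords
    grid <- patterns@gridShape
    if (is.null(centers)) centers <- seq_len(nrow(coords))
    key <- function(xyz)
        xyz[, 1L] + grid[1L] * (xyz[, 2L] + grid[2L] * xyz[, 3L])
    voxKey <- key(coords)
    off <- sphereOffsets(radius)
    acc <- rep(NA_real_, nrow(coords))
    for (v in centers) {
        cand <- sweep(off, 2L, coords[v, ], "+")
        ok <- cand[, 1L] >= 0 & cand[, 1L] < grid[1L] &
              cand[, 2L] >= 0 & cand[, 2L] < grid[2L] &
              cand[, 3L] >= 0 & cand[, 3L] < grid[3L]
        nb <- match(key(cand[ok, , drop = FALSE]), voxKey)
        nb <- nb[!is.na(nb)]
        if (!length(nb)) next
        res <- crossDecodeROI(patterns, target = target,
                              clutter = clutter, scheme = scheme,
                              nBins = nBins, seed = seed, voxels = nb,
                              cost = cost)
        acc[v] <- accuracy(res)
    }
    new("SearchlightVolume", accuracy = acc, voxelCoords = coords,
        gridShape = grid, sphereRadius = as.numeric(radius),
        target = target, clutter = clutter)
}

#' Sensor-space searchlight cross-decoding
#'
#' Runs the time-resolved cross-decoding of [crossDecodeTimecourse()] on
#' the \code{k} channels closest to each channel (by layout distance,
#' excluding the centre channel itself by default) and stores the
#' accuracy time course at the centre channel. The time axis is
#' down-sampled to \code{stepMs} resolution (bin means) before decoding.
#'
#' @inheritParams crossDecodeTimecourse
#' @param k neighborhood size in channels (default 5).
#' @param includeCenter also include the centre channel in the feature
#'   set (default \code{FALSE}: the k closest channels surrounding it).
#' @param stepMs temporal down-sampling step in ms (default 10).
#' @return A [SearchlightChannelMap-class].
#' @export
searchlightChannels <- function(epochs, target = c("location", "category"),
                                clutter, scheme = NULL, k = 5,
                                includeCenter = FALSE, stepMs = 10,
                                nBins = 4, nIterations = 100, seed,
                                cost = 1) {
    target <- match.arg(target)
    validObject(epochs)
    nCh <- dim(epochs@data)[2L]
    if (k >= nCh)
        stop("neighborhood size k must be smaller than the channel count")
    if (anyDuplicated(epochs@layout))
        stop("ambiguous neighborhood: duplicate channel positions")
    ds <- downsampleTime(epochs, stepMs)
    D <- as.matrix(stats::dist(epochs@layout))
    chNames <- rownames(epochs@layout)
    if (is.null(chNames)) chNames <- paste0("ch", seq_len(nCh))
    acc <- NULL
    for (c0 in seq_len(nCh)) {
        ord <- setdiff(order(D[c0, ], seq_len(nCh)), c0)
        sel <- if (includeCenter) c(c0, ord[seq_len(k - 1L)])
               else ord[seq_len(k)]
        sub <- new("EEGEpochSet",
                   data = ds@data[, sel, , drop = FALSE],
                   labels = ds@labels, timeMs = ds@timeMs,
                   layout = ds@layout[sel, , drop = FALSE],
                   design = ds@design)
        res <- crossDecodeTimecourse(sub, target = target,
                                     clutter = clutter, scheme = scheme,
                                     nBins = nBins,
                                     nIterations = nIterations,
                                     seed = seed, cost = cost)
        if (is.null(acc))
            acc <- matrix(NA_real_, nCh, length(accuracy(res)))
        acc[c0, ] <- accuracy(res)
    }
    new("SearchlightChannelMap", accuracy = acc, timeMs = ds@timeMs,
        channelNames = chNames, neighborhoodSize = as.integer(k),
        target = target, clutter = clutter)
}
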