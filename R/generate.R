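#' Per-clutter signal parameter table
#'
#' Convenience constructor for the per-clutter-level parameters of a
#' planted signal component: a Gaussian temporal bump (latency = mean,
#' width = full width at half maximum) carried by spatial patterns of a
#' given amplitude, of which \code{invariantFraction} is shared across
#' the levels of the other factor.
#'
#' @param clutter character vector of clutter levels.
#' @param latencyMs,widthMs,amplitude,invariantFraction numeric vectors
#'   (recycled to the number of clutter levels).
#' @return A data.frame, one row per clutter level.
#' @export
signalTable <- function(clutter, latencyMs, widthMs = 100,
                        amplitude = 1, invariantFraction = 0.6) {
    data.frame(clutter = clutter, latencyMs = latencyMs,
               widthMs = widthMs, amplitude = amplitude,
               invariantFraction = invariantFraction,
               stringsAsFactors = FALSE)
}

.defaultLocationSignal <- function(clutter) {
    # latencies emulate an early location signal that is strongly delayed
    # under heavy background clutter
    lat <- c(140, 133, 317)[seq_along(clutter)]
    lat[is.na(lat)] <- 200
    signalTable(clutter, latencyMs = lat, widthMs = 100, amplitude = 1,
                invariantFraction = 0.6)
}

.defaultCategorySignal <- function(clutter) {
    # category signal peaks later than location and is only mildly delayed
    lat <- c(215, 215, 233)[seq_along(clutter)]
    lat[is.na(lat)] <- 220
    signalTable(clutter, latencyMs = lat, widthMs = 120, amplitude = 1,
                invariantFraction = 0.6)
}

.defaultFmri <- function(clutter) {
    rois <- data.frame(roi = c("V1like", "LOClike"),
                       nVoxels = c(325L, 325L), stringsAsFactors = FALSE)
    snrLoc <- matrix(0, 2, length(clutter),
                     dimnames = list(rois$roi, clutter))
    # early-visual-like voxels carry location only without clutter; the
    # object-selective ROI keeps a clutter-tolerant location signal
    snrLoc["V1like", ] <- c(3, 1.5, 0)[seq_along(clutter)]
    snrLoc["LOClike", ] <- 2
    snrCat <- matrix(0, 2, length(clutter),
                     dimnames = list(rois$roi, clutter))
    snrCat["V1like", ] <- 0.6
    snrCat["LOClike", ] <- 2
    list(nRuns = 10L, rois = rois, gridShape = c(14L, 14L, 8L),
         snrLocation = snrLoc, snrCategory = snrCat)
}

.defaultFeatures <- function(clutter) {
    layers <- paste0("layer", 1:4)
    sepLoc <- matrix(0, 4, length(clutter),
                     dimnames = list(layers, clutter))
    # without clutter location is linearly decodable everywhere; under
    # clutter it emerges gradually along the hierarchy
    sepLoc[, 1L] <- 2
    if (length(clutter) >= 2L) sepLoc[, 2L] <- c(1, 1.25, 1.5, 2)
    if (length(clutter) >= 3L) sepLoc[, 3L] <- c(0.1, 0.5, 1, 2)
    sepCat <- matrix(rep(c(0.2, 0.5, 1, 1.5), length(clutter)), 4,
                     dimnames = list(layers, clutter))
    list(layerNames = layers, nUnits = 128L,
         sepLocation = sepLoc, sepCategory = sepCat)
}

#' Construct a synthetic-data generator configuration
#'
#' Builds a [GeneratorConfig-class] describing planted location and
#' category signals for EEG epochs, fMRI t-value patterns and layer-wise
#' feature activations. The defaults emulate a 63-channel, 1 kHz EEG
#' recording epoched from -100 to 999 ms, a two-ROI fMRI experiment with
#' 10 runs and 325 voxels per ROI, and a four-layer feature hierarchy.
#' The default location signal peaks at 140/133/317 ms in the
#' no/low/high-clutter conditions, and the fMRI SNR map plants location
#' information in the early-visual-like ROI only without clutter but
#' clutter-tolerant location information in the object-selective ROI.
#'
#' @param design a [DesignSpec-class].
#' @param nChannels EEG channel count.
#' @param samplingRate EEG sampling rate in Hz.
#' @param epochWindow epoch (start, end) in ms.
#' @param locationSignal,categorySignal per-clutter signal tables from
#'   [signalTable()]; defaults as described above.
#' @param noise list with \code{channelCorrelation} (correlation between
#'   neighboring channels, decaying exponentially with layout distance),
#'   \code{temporalSmoothingMs} (moving-average width) and \code{sd}.
#' @param fmri,features parameter lists; see [GeneratorConfig-class].
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(design = designSpec(),
                            nChannels = 63,
                            samplingRate = 1000,
                            epochWindow = c(-100, 999),
                            locationSignal = NULL,
                            categorySignal = NULL,
                            noise = list(channelCorrelation = 0.3,
                                         temporalSmoothingMs = 10,
                                         sd = 1),
                            fmri = NULL,
                            features = NULL) {
    cl <- design@clutterLevels
    if (is.null(locationSignal)) locationSignal <- .defaultLocationSignal(cl)
    if (is.null(categorySignal)) categorySignal <- .defaultCategorySignal(cl)
    if (is.null(fmri)) fmri <- .defaultFmri(cl)
    if (is.null(features)) features <- .defaultFeatures(cl)
    new("GeneratorConfig", design = design,
        nChannels = as.integer(nChannels),
        samplingRate = as.numeric(samplingRate),
        epochWindow = as.numeric(epochWindow),
        locationSignal = locationSignal,
        categorySignal = categorySignal,
        noise = noise, fmri = fmri, features = features)
}

# Concentric-ring cap layout; deterministic in the channel count.
.capLayout <- function(n) {
    pos <- matrix(0, n, 2L)
    placed <- 1L
    ring <- 1L
    while (placed < n) {
        k <- min(n - placed, 6L * ring)
        ang <- 2 * pi * (seq_len(k) - 1L) / k + 0.2 * ring
        pos[placed + seq_len(k), ] <- cbind(ring * cos(ang),
                                            ring * sin(ang))
        placed <- placed + k
        ring <- ring + 1L
    }
    rownames(pos) <- paste0("ch", seq_len(n))
    pos
}

# Cholesky factor of the exponential-decay channel noise covariance.
.noiseChol <- function(layout, rho) {
    n <- nrow(layout)
    if (rho <= 0) return(diag(n))
    d <- as.matrix(stats::dist(layout))
    d0 <- min(d[d > 0])
    C <- rho^(d / d0)
    t(chol(C + diag(1e-8, n)))
}

# Mix a shared and a specific pattern: `frac` of the pattern survives a
# change of the other factor's level.
.mixPattern <- function(shared, specific, frac) {
    frac * shared + (1 - frac) * specific
}

.trialLabels <- function(design) {
    conds <- enumerateConditions(design, "exemplar")
    reps <- design@nRuns * design@trialsPerConditionPerRun
    labs <- do.call(rbind, replicate(reps, conds, simplify = FALSE))
    labs$run <- rep(seq_len(design@nRuns),
                    each = nrow(conds) * design@trialsPerConditionPerRun)
    rownames(labs) <- NULL
    labs[, c("run", "clutter", "location", "category", "exemplar")]
}

#' Generate a synthetic EEG epoch set
#'
#' Simulates epoched EEG with planted location and category signals.
#' Each trial is the sum of (i) a location signal: a spatial topography
#' specific to the trial's location (of which the configured invariant
#' fraction is shared across categories -- the component that
#' cross-decoding across category can transfer on) times a Gaussian
#' temporal bump scaled by the clutter-specific amplitude; (ii) an
#' analogous category signal with the factor roles swapped; and (iii)
#' spatially correlated, temporally smoothed Gaussian noise. Trial counts
#' are balanced: every exemplar-level condition appears
#' \code{nRuns * trialsPerConditionPerRun} times.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed; fixes all randomness.
#' @return An [EEGEpochSet-class].
#' @examples
#' cfg <- generatorConfig(designSpec(nRuns = 4), nChannels = 8,
#'                        samplingRate = 100, epochWindow = c(-100, 490))
#' ep <- generateEEG(cfg, seed = 1)
#' dim(epochData(ep))
#' @export
generateEEG <- function(config, seed) {
    validObject(config)
    d <- config@design
    labs <- .trialLabels(d)
    nTrials <- nrow(labs)
    nCh <- config@nChannels
    timeMs <- seq(config@epochWindow[1L], config@epochWindow[2L],
                  by = 1000 / config@samplingRate)
    nT <- length(timeMs)
    layout <- .capLayout(nCh)
    nLoc <- length(d@locations); nCat <- length(d@categories)

    A <- withSeed(seed, {
        sharedLoc <- .unitRows(nLoc, nCh)
        specLoc <- array(t(.unitRows(nLoc * nCat, nCh)),
                         c(nCh, nLoc, nCat))
        sharedCat <- .unitRows(nCat, nCh)
        specCat <- array(t(.unitRows(nCat * nLoc, nCh)),
                         c(nCh, nCat, nLoc))

        L <- .noiseChol(layout, config@noise$channelCorrelation)
        sdN <- config@noise$sd
        w <- max(1L, round(config@noise$temporalSmoothingMs *
                           config@samplingRate / 1000))
        A <- array(0, c(nCh, nT, nTrials))
        if (sdN > 0) {
            for (i in seq_len(nTrials)) {
                E <- L %*% matrix(stats::rnorm(nCh * nT), nCh, nT)
                if (w > 1L) {
                    E <- t(stats::filter(t(E), rep(1, w) / w, sides = 2,
                                         circular = TRUE)) * sqrt(w)
                }
                A[, , i] <- E * sdN
            }
        }

        ls <- config@locationSignal; cs <- config@categorySignal
        for (ci in seq_len(nrow(ls))) {
            clut <- ls$clutter[ci]
            bumpL <- .bump(timeMs, ls$latencyMs[ci], ls$widthMs[ci])
            csr <- cs[cs$clutter == clut, ]
            bumpC <- .bump(timeMs, csr$latencyMs, csr$widthMs)
            for (li in seq_len(nLoc)) for (ki in seq_len(nCat)) {
                idx <- which(labs$clutter == clut &
                             labs$location == d@locations[li] &
                             labs$category == d@categories[ki])
                if (!length(idx)) next
                topoL <- .mixPattern(sharedLoc[li, ], specLoc[, li, ki],
                                     ls$invariantFraction[ci])
                topoC <- .mixPattern(sharedCat[ki, ], specCat[, ki, li],
                                     csr$invariantFraction)
                sig <- ls$amplitude[ci] * outer(topoL, bumpL) +
                       csr$amplitude * outer(topoC, bumpC)
                for (i in idx) A[, , i] <- A[, , i] + sig
            }
        }
        A
    })

    new("EEGEpochSet", data = aperm(A, c(3L, 1L, 2L)), labels = labs,
        timeMs = timeMs, layout = layout, design = d)
}

#' Generate a synthetic fMRI pattern set
#'
#' Simulates run-wise condition-specific t-value patterns on a labelled
#' voxel grid. For each ROI, each condition's pattern is the sum of a
#' location pattern scaled by the ROI x clutter location SNR, a category
#' pattern scaled by the category SNR, and unit-variance Gaussian noise
#' drawn independently per run. The per-ROI x clutter SNR maps allow
#' planting spatial dissociations, e.g. location information present in
#' early-visual-like voxels only without clutter but clutter-tolerant in
#' object-selective voxels.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed.
#' @return An [FMRIPatternSet-class].
#' @export
generateFMRI <- function(config, seed) {
    validObject(config)
    d <- config@design
    fm <- config@fmri
    conds <- enumerateConditions(d, "category")
    nCond <- nrow(conds)
    nRuns <- fm$nRuns
    rois <- fm$rois
    nVoxTot <- sum(rois$nVoxels)
    grid <- as.integer(fm$gridShape)
    coords <- as.matrix(expand.grid(x = seq_len(grid[1L]) - 1L,
                                    y = seq_len(grid[2L]) - 1L,
                                    z = seq_len(grid[3L]) - 1L))
    coords <- coords[seq_len(nVoxTot), , drop = FALSE]
    roiLabels <- rep(rois$roi, rois$nVoxels)
    nLoc <- length(d@locations); nCat <- length(d@categories)
    fLoc <- config@locationSignal$invariantFraction[1L]
    fCat <- config@categorySignal$invariantFraction[1L]

    data <- withSeed(seed, {
        data <- array(stats::rnorm(nRuns * nCond * nVoxTot),
                      c(nRuns, nCond, nVoxTot))
        for (r in seq_len(nrow(rois))) {
            vox <- which(roiLabels == rois$roi[r])
            nv <- length(vox)
            sharedLoc <- .unitRows(nLoc, nv)
            specLoc <- array(t(.unitRows(nLoc * nCat, nv)),
                             c(nv, nLoc, nCat))
            sharedCat <- .unitRows(nCat, nv)
            specCat <- array(t(.unitRows(nCat * nLoc, nv)),
                             c(nv, nCat, nLoc))
            for (ci in seq_len(nCond)) {
                li <- match(conds$location[ci], d@locations)
                ki <- match(conds$category[ci], d@categories)
                clut <- conds$clutter[ci]
                pat <- fm$snrLocation[rois$roi[r], clut] *
                           .mixPattern(sharedLoc[li, ], specLoc[, li, ki],
                                       fLoc) +
                       fm$snrCategory[rois$roi[r], clut] *
                           .mixPattern(sharedCat[ki, ], specCat[, ki, li],
                                       fCat)
                for (run in seq_len(nRuns))
                    data[run, ci, vox] <- data[run, ci, vox] + pat
            }
        }
        data
    })

    new("FMRIPatternSet", data = data, conditionLabels = conds,
        voxelCoords = coords, roiLabels = roiLabels, gridShape = grid)
}

#' Generate synthetic layer-wise feature activations
#'
#' Simulates unit activations of a layered feature hierarchy with
#' location (and category) separability controlled per layer and clutter
#' level, so that e.g. "location information emerges gradually along the
#' hierarchy under clutter" can be planted and recovered by the decoder.
#' Trial structure matches the EEG generator (balanced conditions).
#'
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed.
#' @return A [FeatureActivationSet-class].
#' @export
generateFeatures <- function(config, seed) {
    validObject(config)
    d <- config@design
    ft <- config@features
    labs <- .trialLabels(d)
    nTrials <- nrow(labs)
    nU <- ft$nUnits
    nLoc <- length(d@locations); nCat <- length(d@categories)
    fLoc <- config@locationSignal$invariantFraction[1L]
    fCat <- config@categorySignal$invariantFraction[1L]

    data <- withSeed(seed, {
        out <- list()
        for (ly in ft$layerNames) {
            sharedLoc <- .unitRows(nLoc, nU)
            specLoc <- array(t(.unitRows(nLoc * nCat, nU)),
                             c(nU, nLoc, nCat))
            sharedCat <- .unitRows(nCat, nU)
            specCat <- array(t(.unitRows(nCat * nLoc, nU)),
                             c(nU, nCat, nLoc))
            m <- matrix(stats::rnorm(nTrials * nU), nTrials, nU)
            for (li in seq_len(nLoc)) for (ki in seq_len(nCat)) {
                for (clut in d@clutterLevels) {
                    idx <- which(labs$clutter == clut &
                                 labs$location == d@locations[li] &
                                 labs$category == d@categories[ki])
                    if (!length(idx)) next
                    pat <- ft$sepLocation[ly, clut] *
                               .mixPattern(sharedLoc[li, ],
                                           specLoc[, li, ki], fLoc) +
                           ft$sepCategory[ly, clut] *
                               .mixPattern(sharedCat[ki, ],
                                           specCat[, ki, li], fCat)
                    m[idx, ] <- m[idx, ] + rep(pat, each = length(idx))
                }
            }
            out[[ly]] <- m
        }
        out
    })

    new("FeatureActivationSet", data = data, labels = labs,
        layerNames = ft$layerNames)
}
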