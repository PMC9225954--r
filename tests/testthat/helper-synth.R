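# Small synthetic configurations used across the suite. Signal latencies
# keep the study's qualitative structure (early location signal without
# clutter, delayed under clutter) at sizes that decode in seconds.

smallDesign <- function(nRuns = 4, clutter = c("no", "high"),
                        exemplars = 3) {
    designSpec(nRuns = nRuns, clutterLevels = clutter,
               exemplarsPerCategory = exemplars)
}

smallConfig <- function(design = smallDesign(), nChannels = 10,
                        samplingRate = 100, window = c(-100, 390),
                        locAmplitude = 1, catAmplitude = 1,
                        locLatency = NULL, catLatency = NULL,
                        locFraction = 0.6, catFraction = 0.6,
                        noiseSd = 1, channelCorrelation = 0.3) {
    cl <- design@clutterLevels
    clamp <- function(x) pmin(pmax(x, window[1L]), window[2L])
    if (is.null(locLatency))
        locLatency <- clamp(c(no = 140, low = 160, high = 250)[cl])
    if (is.null(catLatency))
        catLatency <- clamp(c(no = 215, low = 215, high = 233)[cl])
    generatorConfig(
        design, nChannels = nChannels, samplingRate = samplingRate,
        epochWindow = window,
        locationSignal = signalTable(cl, locLatency, widthMs = 80,
                                     amplitude = locAmplitude,
                                     invariantFraction = locFraction),
        categorySignal = signalTable(cl, catLatency, widthMs = 80,
                                     amplitude = catAmplitude,
                                     invariantFraction = catFraction),
        noise = list(channelCorrelation = channelCorrelation,
                     temporalSmoothingMs = 10, sd = noiseSd))
}

nullConfig <- function(design = smallDesign(), ...) {
    smallConfig(design, locAmplitude = 0, catAmplitude = 0, ...)
}

tinyFmri <- function(clutter, nVoxels = c(40L, 40L),
                     grid = c(6L, 6L, 3L), scale = 1) {
    rois <- data.frame(roi = c("V1like", "LOClike"), nVoxels = nVoxels,
                       stringsAsFactors = FALSE)
    snrLoc <- matrix(0, 2, length(clutter),
                     dimnames = list(rois$roi, clutter))
    snrLoc["V1like", ] <- scale * c(3, 1.5, 0)[seq_along(clutter)]
    snrLoc["LOClike", ] <- scale * 2
    snrCat <- matrix(0.5, 2, length(clutter),
                     dimnames = list(rois$roi, clutter))
    list(nRuns = 10L, rois = rois, gridShape = grid,
         snrLocation = snrLoc, snrCategory = snrCat)
}

# Feature set with hand-set activations: one layer, one clutter level,
# one trial per (category, location) pattern repeated `reps` times.
handFeatureSet <- function(patterns, reps = 2) {
    labs <- do.call(rbind, lapply(names(patterns), function(key) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
        data.frame(category = parts[1L], location = parts[2L],
                   clutter = "no", stringsAsFactors = FALSE)
    }))
    labs <- labs[rep(seq_len(nrow(labs)), each = reps), ]
    rownames(labs) <- NULL
    X <- do.call(rbind, lapply(patterns, function(p)
        matrix(rep(p, reps), nrow = reps, byrow = TRUE)))
    new("FeatureActivationSet", data = list(L1 = X), labels = labs,
        layerNames = "L1")
}

twoByTwoScheme <- function(categories = c("A", "B"),
                           locations = c("left-up", "right-up")) {
    buildPairScheme(designSpec(
        categories = categories, exemplarsPerCategory = 1,
        locations = locations,
        locationOffsets = rbind(c(-3, 3), c(3, 3)),
        clutterLevels = "no", nRuns = 1,
        trialsPerConditionPerRun = 1))
}
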