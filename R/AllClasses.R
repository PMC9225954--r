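#' @import methods
NULL

.noDup <- function(x) !anyDuplicated(x)

#' Experimental design specification
#'
#' A \code{DesignSpec} describes a fully crossed visual experiment with
#' factors of object category, object location (screen quadrant, given as
#' signed horizontal/vertical offsets in degrees visual angle) and
#' background clutter, together with the number of runs and the number of
#' trials each exemplar-level condition receives per run.
#'
#' @slot categories ordered character vector of category names.
#' @slot exemplarsPerCategory integer, exemplars per category.
#' @slot locations ordered character vector of quadrant names.
#' @slot locationOffsets numeric matrix (one row per location, columns
#'   \code{h} and \code{v}) of signed offsets in degrees visual angle.
#' @slot clutterLevels ordered character vector of background clutter levels.
#' @slot nRuns integer, number of runs.
#' @slot trialsPerConditionPerRun integer, presentations of each
#'   exemplar-level condition per run.
#'
#' @seealso [designSpec()], [enumerateConditions()], [buildPairScheme()]
#' @export
setClass("DesignSpec",
    representation(
        categories = "character",
        exemplarsPerCategory = "integer",
        locations = "character",
        locationOffsets = "matrix",
        clutterLevels = "character",
        nRuns = "integer",
        trialsPerConditionPerRun = "integer"
    )
)

setValidity("DesignSpec", function(object) {
    msg <- character(0)
    if (length(object@categories) < 1L || !.noDup(object@categories))
        msg <- c(msg, "'categories' must be non-empty and duplicate-free")
    if (length(object@locations) < 1L || !.noDup(object@locations))
        msg <- c(msg, "'locations' must be non-empty and duplicate-free")
    if (length(object@clutterLevels) < 1L || !.noDup(object@clutterLevels))
        msg <- c(msg, "'clutterLevels' must be non-empty and duplicate-free")
    if (nrow(object@locationOffsets) != length(object@locations))
        msg <- c(msg, "'locationOffsets' must have one row per location")
    if (ncol(object@locationOffsets) != 2L)
        msg <- c(msg, "'locationOffsets' must have two columns (h, v)")
    if (!all(is.finite(object@locationOffsets)))
        msg <- c(msg, "location offsets must be finite")
    if (object@exemplarsPerCategory < 1L)
        msg <- c(msg, "'exemplarsPerCategory' must be >= 1")
    if (object@nRuns < 1L || object@trialsPerConditionPerRun < 1L)
        msg <- c(msg, "'nRuns' and 'trialsPerConditionPerRun' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Pairwise classification scheme
#'
#' A \code{PairScheme} enumerates the binary classification cells of the
#' cross-decoding design: all unordered location pairs and all ordered
#' (train, test) category pairs with distinct members. Under the default
#' design (4 locations, 4 categories) this yields 6 location pairs and 12
#' category train/test pairs, i.e. 72 cells.
#'
#' @slot locationPairs character matrix, one unordered location pair per row.
#' @slot categoryTrainTestPairs character matrix, one ordered
#'   (train, test) category pair per row.
#' @slot subset one of \code{"all"}, \code{"cross_hemifield"},
#'   \code{"within_hemifield"}.
#'
#' @seealso [buildPairScheme()], [schemeCellCount()]
#' @export
setClass("PairScheme",
    representation(
        locationPairs = "matrix",
        categoryTrainTestPairs = "matrix",
        subset = "character"
    )
)

setValidity("PairScheme", function(object) {
    msg <- character(0)
    if (ncol(object@locationPairs) != 2L)
        msg <- c(msg, "'locationPairs' must have two columns")
    if (ncol(object@categoryTrainTestPairs) != 2L)
        msg <- c(msg, "'categoryTrainTestPairs' must have two columns")
    if (any(object@categoryTrainTestPairs[, 1L] ==
            object@categoryTrainTestPairs[, 2L]))
        msg <- c(msg, "train and test categories must differ")
    if (any(object@locationPairs[, 1L] == object@locationPairs[, 2L]))
        msg <- c(msg, "location pairs must have distinct members")
    if (!object@subset %in% c("all", "cross_hemifield", "within_hemifield"))
        msg <- c(msg, "unknown 'subset'")
    if (length(msg)) msg else TRUE
})

#' Synthetic-data generator configuration
#'
#' Bundles a [DesignSpec-class] with the parameters of the planted EEG,
#' fMRI and feature signals. Signal components are Gaussian temporal bumps
#' (latency = mean in ms, width = full width at half maximum) carried by
#' random spatial patterns; the \code{invariantFraction} of a location
#' pattern is shared across categories (and vice versa), which is the
#' component cross-decoding can transfer on.
#'
#' @slot design a [DesignSpec-class].
#' @slot nChannels integer, EEG channel count.
#' @slot samplingRate numeric, EEG sampling rate in Hz.
#' @slot epochWindow numeric length-2, epoch start/end in ms.
#' @slot locationSignal data.frame with one row per clutter level and
#'   columns \code{clutter}, \code{latencyMs}, \code{widthMs},
#'   \code{amplitude}, \code{invariantFraction}.
#' @slot categorySignal as \code{locationSignal}, for the category signal.
#' @slot noise list with \code{channelCorrelation} (neighbor correlation in
#'   [0,1)), \code{temporalSmoothingMs} and \code{sd}.
#' @slot fmri list with \code{nRuns}, \code{rois} (data.frame \code{roi},
#'   \code{nVoxels}), \code{gridShape}, \code{snrLocation} and
#'   \code{snrCategory} (ROI x clutter matrices).
#' @slot features list with \code{layerNames}, \code{nUnits},
#'   \code{sepLocation} and \code{sepCategory} (layer x clutter matrices).
#'
#' @seealso [generatorConfig()], [generateEEG()], [generateFMRI()],
#'   [generateFeatures()]
#' @export
setClass("GeneratorConfig",
    representation(
        design = "DesignSpec",
        nChannels = "integer",
        samplingRate = "numeric",
        epochWindow = "numeric",
        locationSignal = "data.frame",
        categorySignal = "data.frame",
        noise = "list",
        fmri = "list",
        features = "list"
    )
)

.validSignalTable <- function(tab, clutter, window, what) {
    msg <- character(0)
    need <- c("clutter", "latencyMs", "widthMs", "amplitude",
              "invariantFraction")
    if (!all(need %in% names(tab)))
        return(sprintf("'%s' must have columns %s", what,
                       paste(need, collapse = ", ")))
    if (!setequal(tab$clutter, clutter))
        msg <- c(msg, sprintf("'%s' must have one row per clutter level",
                              what))
    if (any(tab$amplitude < 0))
        msg <- c(msg, sprintf("'%s' amplitudes must be >= 0", what))
    if (any(tab$invariantFraction < 0 | tab$invariantFraction > 1))
        msg <- c(msg, sprintf("'%s' invariant fractions must be in [0,1]",
                              what))
    bad <- tab$amplitude > 0 &
        (tab$latencyMs < window[1L] | tab$latencyMs > window[2L])
    if (any(bad))
        msg <- c(msg, sprintf("'%s' latencies must lie inside epochWindow",
                              what))
    msg
}

setValidity("GeneratorConfig", function(object) {
    msg <- character(0)
    if (object@nChannels < 2L)
        msg <- c(msg, "'nChannels' must be >= 2")
    if (object@samplingRate <= 0)
        msg <- c(msg, "'samplingRate' must be > 0")
    if (length(object@epochWindow) != 2L ||
        diff(object@epochWindow) <= 0)
        msg <- c(msg, "'epochWindow' must be increasing (start, end) ms")
    cl <- object@design@clutterLevels
    msg <- c(msg,
             .validSignalTable(object@locationSignal, cl,
                               object@epochWindow, "locationSignal"),
             .validSignalTable(object@categorySignal, cl,
                               object@epochWindow, "categorySignal"))
    nz <- object@noise
    if (!all(c("channelCorrelation", "temporalSmoothingMs", "sd") %in%
             names(nz)))
        msg <- c(msg, "'noise' must list channelCorrelation, temporalSmoothingMs, sd")
    else if (nz$channelCorrelation < 0 || nz$channelCorrelation >= 1)
        msg <- c(msg, "'noise$channelCorrelation' must be in [0, 1)")
    fm <- object@fmri
    if (!is.null(fm$rois)) {
        if (!setequal(rownames(fm$snrLocation), fm$rois$roi) ||
            !setequal(rownames(fm$snrCategory), fm$rois$roi))
            msg <- c(msg, "fmri SNR maps must cover exactly the listed ROIs")
        if (!all(cl %in% colnames(fm$snrLocation)) ||
            !all(cl %in% colnames(fm$snrCategory)))
            msg <- c(msg, "fmri SNR maps must have one column per clutter level")
        if (prod(fm$gridShape) < sum(fm$rois$nVoxels))
            msg <- c(msg, "fmri grid too small for the requested voxels")
    }
    if (length(msg)) msg else TRUE
})

#' EEG epoch container
#'
#' Trials x channels x timepoints tensor with per-trial condition labels,
#' a uniform time axis in ms relative to stimulus onset, and a 2-D channel
#' layout used by the sensor-space searchlight.
#'
#' @slot data numeric array, trials x channels x timepoints.
#' @slot labels data.frame with columns \code{run}, \code{category},
#'   \code{exemplar}, \code{location}, \code{clutter} (one row per trial).
#' @slot timeMs numeric time axis in ms.
#' @slot layout numeric matrix, channels x 2 positions (arbitrary units).
#' @slot design the generating [DesignSpec-class].
#'
#' @seealso [generateEEG()], [noiseNormalize()], [crossDecodeTimecourse()]
#' @export
setClass("EEGEpochSet",
    representation(
        data = "array",
        labels = "data.frame",
        timeMs = "numeric",
        layout = "matrix",
        design = "DesignSpec"
    )
)

setValidity("EEGEpochSet", function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "'data' must be a trials x channels x time array")
    if (nrow(object@labels) != d[1L])
        msg <- c(msg, "one label row per trial required")
    if (length(object@timeMs) != d[3L])
        msg <- c(msg, "'timeMs' must match the time dimension")
    if (length(object@timeMs) > 1L) {
        st <- diff(object@timeMs)
        if (any(st <= 0) || max(abs(st - st[1L])) > 1e-6)
            msg <- c(msg, "'timeMs' must be strictly increasing and uniform")
    }
    if (nrow(object@layout) != d[2L])
        msg <- c(msg, "'layout' must have one row per channel")
    if (length(msg)) msg else TRUE
})

#' fMRI pattern container
#'
#' Run-wise condition-specific voxel patterns on a t-value scale:
#' a runs x conditions x voxels tensor, the condition labels in canonical
#' enumeration order, integer 3-D grid coordinates and a per-voxel ROI
#' label.
#'
#' @slot data numeric array, runs x conditions x voxels.
#' @slot conditionLabels data.frame (one row per condition; columns
#'   \code{clutter}, \code{location}, \code{category}).
#' @slot voxelCoords integer matrix, voxels x 3 grid coordinates.
#' @slot roiLabels character vector, per-voxel ROI name.
#' @slot gridShape integer length-3 extent of the voxel grid.
#'
#' @seealso [generateFMRI()], [crossDecodeROI()], [searchlightVolume()]
#' @export
setClass("FMRIPatternSet",
    representation(
        data = "array",
        conditionLabels = "data.frame",
        voxelCoords = "matrix",
        roiLabels = "character",
        gridShape = "integer"
    )
)

setValidity("FMRIPatternSet", function(object) {
    msg <- character(0)
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "'data' must be a runs x conditions x voxels array")
    if (nrow(object@conditionLabels) != d[2L])
        msg <- c(msg, "one label row per condition required")
    if (nrow(object@voxelCoords) != d[3L] ||
        length(object@roiLabels) != d[3L])
        msg <- c(msg, "coordinates and ROI labels must match voxel count")
    if (anyDuplicated(object@voxelCoords))
        msg <- c(msg, "voxel coordinates must be unique")
    if (length(msg)) msg else TRUE
})

#' Layer-wise feature activation container
#'
#' Per-layer trials x units activation matrices sharing one trial
#' labelling, as produced by a feed-forward feature hierarchy.
#'
#' @slot data named list of numeric matrices (trials x units), one per layer.
#' @slot labels data.frame, one row per trial.
#' @slot layerNames ordered character vector of layer names.
#'
#' @seealso [generateFeatures()], [crossDecodeFeatures()]
#' @export
setClass("FeatureActivationSet",
    representation(
        data = "list",
        labels = "data.frame",
        layerNames = "character"
    )
)

setValidity("FeatureActivationSet", function(object) {
    msg <- character(0)
    if (!setequal(names(object@data), object@layerNames))
        msg <- c(msg, "'data' must be named by 'layerNames'")
    n <- vapply(object@data, nrow, integer(1))
    if (length(unique(n)) > 1L)
        msg <- c(msg, "all layers must have the same trial count")
    if (length(n) && n[[1L]] != nrow(object@labels))
        msg <- c(msg, "one label row per trial required")
    if (length(msg)) msg else TRUE
})

#' Cross-decoding result
#'
#' Mean pairwise cross-classification accuracy (percent, 50\% chance)
#' indexed by ROI name, time point or layer name, together with the
#' per-cell accuracies in canonical scheme order (used to build
#' representational dissimilarity vectors).
#'
#' @slot accuracy named numeric vector of mean accuracies (percent).
#' @slot index character or numeric index (ROI, time in ms, or layer).
#' @slot cellAccuracy numeric matrix, index x scheme cells, mean per-cell
#'   accuracy in canonical order.
#' @slot cellIndex data.frame describing the canonical cell order
#'   (columns \code{classA}, \code{classB}, \code{train}, \code{test}).
#' @slot target \code{"location"} or \code{"category"}.
#' @slot clutter clutter level decoded.
#' @slot nCellsAveraged integer, cells averaged into each accuracy.
#' @slot chance numeric, chance level (50).
#'
#' @export
setClass("DecodingResult",
    representation(
        accuracy = "numeric",
        index = "ANY",
        cellAccuracy = "matrix",
        cellIndex = "data.frame",
        target = "character",
        clutter = "character",
        nCellsAveraged = "integer",
        chance = "numeric"
    )
)

setValidity("DecodingResult", function(object) {
    msg <- character(0)
    if (any(object@accuracy < 0 | object@accuracy > 100, na.rm = TRUE))
        msg <- c(msg, "accuracies must lie in [0, 100]")
    if (length(object@accuracy) != length(object@index))
        msg <- c(msg, "'index' must match 'accuracy' length")
    if (length(msg)) msg else TRUE
})

#' Temporal generalization matrix
#'
#' Train-time x test-time cross-classification accuracies (percent), with
#' uniform axes in ms. Rows are training time points (from the training
#' condition), columns testing time points (from the testing condition).
#'
#' @slot accuracy numeric matrix, train-time x test-time (percent).
#' @slot trainAxisMs,testAxisMs numeric time axes in ms.
#' @slot trainCondition,testCondition clutter names of the two conditions.
#' @slot target decoded factor.
#'
#' @seealso [temporalGeneralization()], [peakToDiagonal()],
#'   [diagonalDifference()]
#' @export
setClass("GeneralizationMatrix",
    representation(
        accuracy = "matrix",
        trainAxisMs = "numeric",
        testAxisMs = "numeric",
        trainCondition = "character",
        testCondition = "character",
        target = "character"
    )
)

setValidity("GeneralizationMatrix", function(object) {
    msg <- character(0)
    if (nrow(object@accuracy) != length(object@trainAxisMs) ||
        ncol(object@accuracy) != length(object@testAxisMs))
        msg <- c(msg, "axes must match matrix dimensions")
    if (any(object@accuracy < 0 | object@accuracy > 100, na.rm = TRUE))
        msg <- c(msg, "accuracies must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' Volumetric searchlight map
#'
#' Per-voxel cross-decoding accuracy obtained by decoding within a sphere
#' of fixed radius (in voxel units) centred on every voxel.
#'
#' @slot accuracy numeric vector, one value per voxel (NA where the
#'   sphere is empty).
#' @slot voxelCoords integer matrix, voxels x 3.
#' @slot gridShape integer length-3.
#' @slot sphereRadius numeric radius in voxels.
#' @slot target,clutter decoding factor and clutter level.
#'
#' @seealso [searchlightVolume()]
#' @export
setClass("SearchlightVolume",
    representation(
        accuracy = "numeric",
        voxelCoords = "matrix",
        gridShape = "integer",
        sphereRadius = "numeric",
        target = "character",
        clutter = "character"
    )
)

#' Sensor-space searchlight map
#'
#' Channel x down-sampled-time cross-decoding accuracies, each computed
#' from the small neighborhood of channels closest to the stored channel.
#'
#' @slot accuracy numeric matrix, channels x time bins (percent).
#' @slot timeMs numeric, bin-center time axis in ms.
#' @slot channelNames character vector.
#' @slot neighborhoodSize integer, channels per searchlight.
#' @slot target,clutter decoding factor and clutter level.
#'
#' @seealso [searchlightChannels()]
#' @export
setClass("SearchlightChannelMap",
    representation(
        accuracy = "matrix",
        timeMs = "numeric",
        channelNames = "character",
        neighborhoodSize = "integer",
        target = "character",
        clutter = "character"
    )
)

#' Representational dissimilarity vector
#'
#' Pairwise cross-decoding accuracies in canonical cell order (under the
#' default design: 6 location pairs x 6 unordered category pairs x 2
#' train/test directions = 72 entries). Higher accuracy is read as larger
#' dissimilarity; no distance transform is applied.
#'
#' @slot values numeric vector of accuracies.
#' @slot entryIndex data.frame describing each entry (columns
#'   \code{classA}, \code{classB}, \code{train}, \code{test}).
#' @slot modality e.g. \code{"eeg"} or \code{"fmri"}.
#' @slot clutter clutter level.
#' @slot tag free-form subject/group tag.
#'
#' @seealso [buildRDV()], [fuseRDVs()], [eegPeakRDV()]
#' @export
setClass("RDV",
    representation(
        values = "numeric",
        entryIndex = "data.frame",
        modality = "character",
        clutter = "character",
        tag = "character"
    )
)

setValidity("RDV", function(object) {
    if (length(object@values) != nrow(object@entryIndex))
        "'entryIndex' must have one row per value" else TRUE
})
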