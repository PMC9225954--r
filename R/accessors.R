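#' Accessors for the data containers
#'
#' Accessor functions for the package's S4 containers; user code should
#' use these instead of reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors trials x channels x time tensor of an
#'   [EEGEpochSet-class].
#' @export
epochData <- function(x) x@data

#' @describeIn accessors per-trial label data.frame.
#' @export
epochLabels <- function(x) x@labels

#' @describeIn accessors time axis in ms.
#' @export
epochTime <- function(x) x@timeMs

#' @describeIn accessors channels x 2 layout matrix.
#' @export
channelLayout <- function(x) x@layout

#' @describeIn accessors runs x conditions x voxels tensor of an
#'   [FMRIPatternSet-class].
#' @export
patternData <- function(x) x@data

#' @describeIn accessors condition label data.frame (canonical order).
#' @export
conditionLabels <- function(x) x@conditionLabels

#' @describeIn accessors voxels x 3 integer grid coordinates.
#' @export
voxelCoordinates <- function(x) x@voxelCoords

#' @describeIn accessors per-voxel ROI labels.
#' @export
roiLabels <- function(x) x@roiLabels

#' @describeIn accessors named list of trials x units matrices of a
#'   [FeatureActivationSet-class].
#' @export
featureData <- function(x) x@data

#' @describeIn accessors ordered layer names.
#' @export
layerNames <- function(x) x@layerNames

#' @describeIn accessors unordered location pairs of a
#'   [PairScheme-class].
#' @export
locationPairs <- function(x) x@locationPairs

#' @describeIn accessors ordered (train, test) category pairs.
#' @export
categoryTrainTestPairs <- function(x) x@categoryTrainTestPairs

#' @describeIn accessors decoded accuracies (percent): a named vector for
#'   [DecodingResult-class], a matrix for [GeneralizationMatrix-class],
#'   [SearchlightVolume-class] and [SearchlightChannelMap-class].
#' @export
accuracy <- function(x) x@accuracy

#' @describeIn accessors index (ROI names, time in ms or layer names) of
#'   a [DecodingResult-class].
#' @export
decodingIndex <- function(x) x@index

#' @describeIn accessors per-cell accuracies in canonical scheme order.
#' @export
cellAccuracy <- function(x) x@cellAccuracy

#' @describeIn accessors entry values of an [RDV-class].
#' @export
rdvValues <- function(x) x@values

#' @describeIn accessors canonical entry index of an [RDV-class].
#' @export
rdvEntryIndex <- function(x) x@entryIndex

#' @describeIn accessors training-time axis (ms) of a
#'   [GeneralizationMatrix-class].
#' @export
trainTimes <- function(x) x@trainAxisMs

#' @describeIn accessors testing-time axis (ms).
#' @export
testTimes <- function(x) x@testAxisMs

#' Subset an EEG epoch set by trial labels
#'
#' @param epochs an [EEGEpochSet-class].
#' @param clutter,category,location optional label values to keep.
#' @param trials optional explicit trial indices.
#' @return An [EEGEpochSet-class] with the selected trials.
#' @export
subsetEpochs <- function(epochs, clutter = NULL, category = NULL,
                         location = NULL, trials = NULL) {
    keep <- rep(TRUE, nrow(epochs@labels))
    if (!is.null(clutter)) keep <- keep & epochs@labels$clutter %in% clutter
    if (!is.null(category)) keep <- keep & epochs@labels$category %in% category
    if (!is.null(location)) keep <- keep & epochs@labels$location %in% location
    idx <- which(keep)
    if (!is.null(trials)) idx <- intersect(idx, trials)
    if (!length(idx)) stop("no trials match the requested subset")
    new("EEGEpochSet", data = epochs@data[idx, , , drop = FALSE],
        labels = epochs@labels[idx, , drop = FALSE],
        timeMs = epochs@timeMs, layout = epochs@layout,
        design = epochs@design)
}

setMethod("show", "DesignSpec", function(object) {
    cat("DesignSpec:",
        length(object@categories), "categories x",
        length(object@locations), "locations x",
        length(object@clutterLevels), "clutter levels,",
        object@exemplarsPerCategory, "exemplars/category\n")
    cat("  categories:", paste(object@categories, collapse = ", "), "\n")
    cat("  locations: ", paste(object@locations, collapse = ", "), "\n")
    cat("  clutter:   ", paste(object@clutterLevels, collapse = ", "), "\n")
    cat("  runs:", object@nRuns, "| trials/condition/run:",
        object@trialsPerConditionPerRun, "\n")
})

setMethod("show", "PairScheme", function(object) {
    cat("PairScheme (subset:", object@subset, "):",
        nrow(object@locationPairs), "location pairs x",
        nrow(object@categoryTrainTestPairs),
        "category train/test pairs =",
        nrow(object@locationPairs) *
            nrow(object@categoryTrainTestPairs), "cells\n")
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig:", object@nChannels, "channels @",
        object@samplingRate, "Hz, epoch",
        object@epochWindow[1L], "...", object@epochWindow[2L], "ms\n")
    cat("  location signal latencies (ms):",
        paste(sprintf("%s=%g", object@locationSignal$clutter,
                      object@locationSignal$latencyMs), collapse = ", "),
        "\n")
})

setMethod("show", "EEGEpochSet", function(object) {
    d <- dim(object@data)
    cat("EEGEpochSet:", d[1L], "trials x", d[2L], "channels x", d[3L],
        "time points (", object@timeMs[1L], "...",
        object@timeMs[d[3L]], "ms )\n")
})

setMethod("show", "FMRIPatternSet", function(object) {
    d <- dim(object@data)
    cat("FMRIPatternSet:", d[1L], "runs x", d[2L], "conditions x",
        d[3L], "voxels; ROIs:",
        paste(unique(object@roiLabels), collapse = ", "), "\n")
})

setMethod("show", "FeatureActivationSet", function(object) {
    cat("FeatureActivationSet:", nrow(object@labels), "trials;",
        length(object@layerNames), "layers (",
        paste(object@layerNames, collapse = ", "), ")\n")
})

setMethod("show", "DecodingResult", function(object) {
    cat("DecodingResult (", object@target, "across",
        ifelse(object@target == "location", "category", "location"),
        ", clutter:", object@clutter, "):",
        length(object@accuracy), "indexed accuracies, mean",
        sprintf("%.1f%%", mean(object@accuracy)), "(chance",
        paste0(object@chance, "%);"),
        object@nCellsAveraged, "cells averaged each\n")
})

setMethod("show", "GeneralizationMatrix", function(object) {
    cat("GeneralizationMatrix:", nrow(object@accuracy), "train x",
        ncol(object@accuracy), "test time points; train",
        object@trainCondition, "-> test", object@testCondition, "\n")
})

setMethod("show", "SearchlightVolume", function(object) {
    cat("SearchlightVolume: radius", object@sphereRadius, "voxels;",
        sum(!is.na(object@accuracy)), "of", length(object@accuracy),
        "voxels decoded\n")
})

setMethod("show", "SearchlightChannelMap", function(object) {
    cat("SearchlightChannelMap:", nrow(object@accuracy), "channels x",
        ncol(object@accuracy), "time bins; neighborhood",
        object@neighborhoodSize, "channels\n")
})

setMethod("show", "RDV", function(object) {
    cat("RDV (", object@modality, ", clutter:", object@clutter, "):",
        length(object@values), "entries, mean",
        sprintf("%.2f", mean(object@values)), "\n")
})
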