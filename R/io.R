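# Container I/O. Epoch and feature sets travel as versioned R
# serialization containers; fMRI pattern sets as a 4-D NIfTI volume plus
# plain-text label sheets; results as tidy TSV.

.EPOCH_FORMAT <- "mvpaFuse-epochs-1"
.PATTERN_FORMAT <- "mvpaFuse-patterns-1"

#' Write / read an EEG epoch set container
#'
#' Serializes an [EEGEpochSet-class] (data tensor, labels, time axis,
#' layout, design) to a single versioned container file; reading
#' restores an identical object. A file with missing datasets raises a
#' format error naming the missing field.
#'
#' @param epochs an [EEGEpochSet-class].
#' @param path file path.
#' @return \code{writeEpochSet}: \code{path} invisibly;
#'   \code{readEpochSet}: the [EEGEpochSet-class].
#' @export
writeEpochSet <- function(epochs, path) {
    validObject(epochs)
    saveRDS(list(format = .EPOCH_FORMAT, data = epochs@data,
                 labels = epochs@labels, timeMs = epochs@timeMs,
                 layout = epochs@layout,
                 design = .designAsList(epochs@design)),
            path)
    invisible(path)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(path) {
    x <- readRDS(path)
    .checkFormat(x, .EPOCH_FORMAT,
                 c("data", "labels", "timeMs", "layout", "design"))
    new("EEGEpochSet", data = x$data, labels = x$labels,
        timeMs = x$timeMs, layout = x$layout,
        design = .designFromList(x$design))
}

.checkFormat <- function(x, format, fields) {
    if (!is.list(x) || is.null(x$format))
        stop("not a ", format, " container (no format marker)")
    if (!identical(x$format, format))
        stop("container format mismatch: expected ", format, ", found ",
             x$format)
    miss <- setdiff(fields, names(x))
    if (length(miss))
        stop("container is missing dataset(s): ",
             paste(miss, collapse = ", "))
}

.designAsList <- function(d) {
    list(categories = d@categories,
         exemplarsPerCategory = d@exemplarsPerCategory,
         locations = d@locations,
         locationOffsets = d@locationOffsets,
         clutterLevels = d@clutterLevels, nRuns = d@nRuns,
         trialsPerConditionPerRun = d@trialsPerConditionPerRun)
}

.designFromList <- function(x) {
    designSpec(categories = x$categories,
               exemplarsPerCategory = x$exemplarsPerCategory,
               locations = x$locations,
               locationOffsets = x$locationOffsets,
               clutterLevels = x$clutterLevels, nRuns = x$nRuns,
               trialsPerConditionPerRun = x$trialsPerConditionPerRun)
}

#' Write / read an fMRI pattern set as NIfTI plus label sheets
#'
#' Writes the runs x conditions x voxels tensor as a 4-D NIfTI-1 volume
#' on the dense voxel grid (volumes ordered run-major: all conditions of
#' run 1, then run 2, ...; off-pattern grid voxels are NA), together
#' with plain-text TSV sheets for the condition labels and the voxel
#' table (grid coordinates and ROI labels). Reading restores the
#' container; grid shape and voxel order are preserved.
#'
#' @param patterns an [FMRIPatternSet-class].
#' @param prefix output path prefix; writes \code{<prefix>.nii},
#'   \code{<prefix>_conditions.tsv} and \code{<prefix>_voxels.tsv}.
#' @return \code{writePatternSet}: \code{prefix} invisibly;
#'   \code{readPatternSet}: the [FMRIPatternSet-class].
#' @export
writePatternSet <- function(patterns, prefix) {
    validObject(patterns)
    d <- dim(patterns@data)
    grid <- patterns@gridShape
    vol <- array(NA_real_, c(grid, d[1L] * d[2L]))
    lin <- 1L + patterns@voxelCoords[, 1L] +
        grid[1L] * (patterns@voxelCoords[, 2L] +
                    grid[2L] * patterns@voxelCoords[, 3L])
    nGrid <- prod(grid)
    v <- 0L
    for (run in seq_len(d[1L])) for (ci in seq_len(d[2L])) {
        v <- v + 1L
        vol[(v - 1L) * nGrid + lin] <- patterns@data[run, ci, ]
    }
    RNifti::writeNifti(RNifti::asNifti(vol), paste0(prefix, ".nii"))
    cl <- patterns@conditionLabels
    cl$conditionIndex <- seq_len(nrow(cl))
    utils::write.table(cl, paste0(prefix, "_conditions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vx <- data.frame(x = patterns@voxelCoords[, 1L],
                     y = patterns@voxelCoords[, 2L],
                     z = patterns@voxelCoords[, 3L],
                     roi = patterns@roiLabels, nRuns = d[1L])
    utils::write.table(vx, paste0(prefix, "_voxels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(prefix)
}

#' @rdname writePatternSet
#' @export
readPatternSet <- function(prefix) {
    nii <- paste0(prefix, ".nii")
    if (!file.exists(nii)) stop("missing dataset: ", nii)
    vol <- as.array(RNifti::readNifti(nii))
    cl <- utils::read.delim(paste0(prefix, "_conditions.tsv"),
                            stringsAsFactors = FALSE)
    vx <- utils::read.delim(paste0(prefix, "_voxels.tsv"),
                            stringsAsFactors = FALSE)
    need <- c("clutter", "location", "category", "conditionIndex")
    miss <- setdiff(need, names(cl))
    if (length(miss))
        stop("condition sheet is missing column(s): ",
             paste(miss, collapse = ", "))
    grid <- dim(vol)[1:3]
    nCond <- nrow(cl)
    nRuns <- vx$nRuns[1L]
    coords <- as.matrix(vx[, c("x", "y", "z")])
    lin <- 1L + coords[, 1L] + grid[1L] * (coords[, 2L] +
                                           grid[2L] * coords[, 3L])
    nGrid <- prod(grid)
    data <- array(0, c(nRuns, nCond, nrow(coords)))
    v <- 0L
    for (run in seq_len(nRuns)) for (ci in seq_len(nCond)) {
        v <- v + 1L
        data[run, ci, ] <- vol[(v - 1L) * nGrid + lin]
    }
    new("FMRIPatternSet", data = data,
        conditionLabels = cl[, c("clutter", "location", "category")],
        voxelCoords = coords, roiLabels = vx$roi,
        gridShape = as.integer(grid))
}

#' Write a searchlight volume as NIfTI
#'
#' @param volume a [SearchlightVolume-class].
#' @param path output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
writeSearchlightNifti <- function(volume, path) {
    grid <- volume@gridShape
    vol <- array(NA_real_, grid)
    lin <- 1L + volume@voxelCoords[, 1L] +
        grid[1L] * (volume@voxelCoords[, 2L] +
                    grid[2L] * volume@voxelCoords[, 3L])
    vol[lin] <- volume@accuracy
    RNifti::writeNifti(RNifti::asNifti(vol), path)
    invisible(path)
}

#' Write / read decoding results as tidy TSV
#'
#' One row per indexed accuracy with columns \code{subject},
#' \code{modality}, \code{target}, \code{clutter}, \code{index},
#' \code{accuracy}, \code{n_cells}, \code{seed}.
#'
#' @param result a [DecodingResult-class].
#' @param path TSV path; for \code{writeDecodingTSV} an existing file is
#'   appended to without repeating the header.
#' @param subject,modality,seed metadata columns.
#' @return \code{writeDecodingTSV}: \code{path} invisibly;
#'   \code{readDecodingTSV}: a data.frame.
#' @export
writeDecodingTSV <- function(result, path, subject = NA,
                             modality = NA_character_, seed = NA) {
    df <- data.frame(subject = subject, modality = modality,
                     target = result@target, clutter = result@clutter,
                     index = result@index, accuracy = result@accuracy,
                     n_cells = result@nCellsAveraged, seed = seed)
    append <- file.exists(path)
    suppressWarnings(
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !append,
                           append = append))
    invisible(path)
}

#' @rdname writeDecodingTSV
#' @export
readDecodingTSV <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
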