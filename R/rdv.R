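#' Build a representational dissimilarity vector
#'
#' Arranges pairwise cross-decoding accuracies into the canonical RDV
#' order: class pairs (e.g. the 6 location pairs, in design order)
#' slowest, then the unordered transfer pairs (e.g. the 6 category
#' pairs), each in both train/test directions. Under the default design
#' this yields 6 x 6 x 2 = 72 entries. Accuracies are used directly as
#' dissimilarities (two conditions are assumed more dissimilar when they
#' are classified more easily); no averaging and no distance transform
#' is applied.
#'
#' @param x either a [DecodingResult-class] (its per-cell accuracies are
#'   used) or a data.frame with columns \code{classA}, \code{classB},
#'   \code{train}, \code{test}, \code{accuracy} covering every canonical
#'   cell exactly once.
#' @param scheme the [PairScheme-class] defining the canonical order
#'   (required for data.frame input; for a [DecodingResult-class] the
#'   stored cell index is used).
#' @param target decoded factor (data.frame input; default
#'   \code{"location"}).
#' @param index for a multi-index [DecodingResult-class] (time course,
#'   layers), which index to extract (default 1).
#' @param modality,clutter,tag metadata carried on the RDV.
#' @return An [RDV-class].
#' @export
buildRDV <- function(x, scheme = NULL, target = "location", index = 1L,
                     modality = "unknown", clutter = "unknown",
                     tag = "") {
    if (is(x, "DecodingResult")) {
        values <- x@cellAccuracy[index, ]
        entry <- x@cellIndex
        clutter <- x@clutter
    } else {
        if (is.null(scheme))
            stop("'scheme' is required to order a plain accuracy table")
        roles <- .schemeRoles(scheme, target)
        entry <- .cellIndex(roles)
        key <- function(d) paste(d$classA, d$classB, d$train, d$test,
                                 sep = "\r")
        # unordered class pair: accept either member order
        keyRev <- function(d) paste(d$classB, d$classA, d$train, d$test,
                                    sep = "\r")
        pos <- match(key(entry), key(x))
        pos2 <- match(key(entry), keyRev(x))
        pos[is.na(pos)] <- pos2[is.na(pos)]
        if (anyNA(pos)) {
            miss <- entry[is.na(pos), , drop = FALSE]
            stop("incomplete RDV: missing cell(s), e.g. (",
                 paste(unlist(miss[1L, ]), collapse = ", "), ")")
        }
        values <- x$accuracy[pos]
    }
    new("RDV", values = as.numeric(values), entryIndex = entry,
        modality = modality, clutter = clutter, tag = tag)
}

#' Average time-resolved RDVs over a peak window and subjects
#'
#' Extracts the RDV at every time point inside a peak-latency confidence
#' window, averages across those time points, and then across subjects,
#' producing one group-level RDV (typically one per background
#' condition) for fusion with subject-specific fMRI RDVs.
#'
#' @param rdvByTime list over subjects; each element a numeric matrix of
#'   time points x RDV entries (e.g. \code{cellAccuracy()} of a
#'   [crossDecodeTimecourse()] result).
#' @param timeMs time axis matching the matrix rows.
#' @param peakCI (low, high) ms window, e.g. a bootstrap CI of the peak
#'   latency.
#' @param entryIndex canonical entry index (data.frame) for the output.
#' @param modality,clutter,tag metadata for the output RDV.
#' @return An [RDV-class] group average.
#' @export
eegPeakRDV <- function(rdvByTime, timeMs, peakCI, entryIndex,
                       modality = "eeg", clutter = "unknown",
                       tag = "group") {
    sel <- which(timeMs >= peakCI[1L] & timeMs <= peakCI[2L])
    if (!length(sel)) stop("empty peak confidence window")
    perSubject <- lapply(rdvByTime, function(m)
        colMeans(m[sel, , drop = FALSE]))
    values <- colMeans(do.call(rbind, perSubject))
    new("RDV", values = values, entryIndex = entryIndex,
        modality = modality, clutter = clutter, tag = tag)
}

#' Fuse two RDVs by rank correlation
#'
#' Spearman rank correlation between an EEG (peak-window, group-mean)
#' RDV and an fMRI (subject- and ROI-specific) RDV over their common
#' canonical entries. High correlation indicates that the time window
#' and the region represent the conditions with similar dissimilarity
#' structure. The correlation is invariant to strictly monotone
#' transforms of either vector.
#'
#' @param eegRDV,fmriRDV [RDV-class] objects with identical entry
#'   indices.
#' @return Spearman correlation (single numeric).
#' @export
fuseRDVs <- function(eegRDV, fmriRDV) {
    if (!identical(eegRDV@entryIndex, fmriRDV@entryIndex))
        stop("RDV entry orders differ; fusion requires identical indices")
    if (stats::sd(eegRDV@values) == 0 || stats::sd(fmriRDV@values) == 0)
        stop("undefined correlation: constant RDV")
    stats::cor(eegRDV@values, fmriRDV@values, method = "spearman")
}
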