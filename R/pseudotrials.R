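#' Pseudo-trial set
#'
#' Result of averaging raw trials (or runs) into pseudo-trials: bins
#' within each condition are disjoint, exhaust the retained trials, and
#' each pseudo-trial is the arithmetic mean of its bin.
#'
#' @slot data numeric matrix, pseudo-trials x features.
#' @slot labels character condition label per pseudo-trial.
#' @slot bin integer bin id per pseudo-trial.
#' @slot assignment integer bin id per raw trial (in input order).
#' @slot seed integer seed used for the random assignment.
#'
#' @seealso [binPseudoTrials()]
#' @export
setClass("PseudoTrialSet",
    representation(data = "matrix", labels = "character",
                   bin = "integer", assignment = "integer",
                   seed = "integer"))

setMethod("show", "PseudoTrialSet", function(object) {
    cat("PseudoTrialSet:", nrow(object@data), "pseudo-trials from",
        length(object@assignment), "raw trials\n")
})

# Random near-equal bin assignment within each condition.
.assignBins <- function(conditions, nBins) {
    conditions <- as.character(conditions)
    out <- integer(length(conditions))
    for (lv in unique(conditions)) {
        idx <- which(conditions == lv)
        m <- length(idx)
        if (m < nBins)
            stop("infeasible binning: condition '", lv, "' has ", m,
                 " trials for ", nBins, " bins")
        out[idx] <- sample(rep_len(seq_len(nBins), m))
    }
    out
}

# Average rows of `x` within (condition, bin) groups; returns a matrix
# with one row per group in (condition, bin) order plus the group keys.
.averageBins <- function(x, conditions, bins) {
    key <- paste(conditions, bins, sep = "\r")
    sums <- rowsum(x, key, reorder = TRUE)
    counts <- as.vector(table(key)[rownames(sums)])
    parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
    list(data = sums / counts, labels = parts[, 1L],
         bin = as.integer(parts[, 2L]))
}

#' Average raw trials into pseudo-trials
#'
#' Randomly assigns the raw trials of each condition to \code{nBins}
#' near-equal bins and averages each bin into one pseudo-trial, raising
#' the signal-to-noise ratio before classification. With 60 trials per
#' condition and 4 bins this produces four pseudo-trials of 15 trials
#' each; the fMRI variant bins 10 runs into five pseudo-runs of two runs.
#' Setting \code{nBins} to the per-condition trial count reduces to a
#' permutation of the raw trials.
#'
#' @param x numeric matrix, raw trials x features.
#' @param conditions condition label per raw trial.
#' @param nBins number of bins (every condition must have at least
#'   \code{nBins} trials).
#' @param seed integer seed.
#' @return A [PseudoTrialSet-class].
#' @export
binPseudoTrials <- function(x, conditions, nBins, seed) {
    stopifnot(is.matrix(x), nrow(x) == length(conditions))
    nBins <- as.integer(nBins)
    assignment <- withSeed(seed, .assignBins(conditions, nBins))
    avg <- .averageBins(x, as.character(conditions), assignment)
    new("PseudoTrialSet", data = avg$data, labels = avg$labels,
        bin = avg$bin, assignment = assignment, seed = as.integer(seed))
}
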