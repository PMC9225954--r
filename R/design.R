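#' Construct an experimental design specification
#'
#' Builds a [DesignSpec-class] for a fully crossed category x location x
#' background-clutter experiment. The defaults describe a 4 x 4 x 3 design
#' with three exemplars per category: four object categories, four screen
#' quadrants whose centres sit 3 degrees visual angle from both central
#' midlines, and three background-clutter levels.
#'
#' @param categories ordered character vector of category names.
#' @param exemplarsPerCategory exemplars per category.
#' @param locations ordered character vector of quadrant names.
#' @param locationOffsets numeric matrix (locations x 2) of signed
#'   (horizontal, vertical) offsets in degrees visual angle.
#' @param clutterLevels ordered character vector of clutter levels.
#' @param nRuns number of runs.
#' @param trialsPerConditionPerRun presentations of each exemplar-level
#'   condition per run.
#'
#' @return A [DesignSpec-class] object.
#' @examples
#' d <- designSpec()
#' nrow(enumerateConditions(d))            # 48
#' nrow(enumerateConditions(d, "exemplar")) # 144
#' @export
designSpec <- function(categories = c("animals", "cars", "faces", "chairs"),
                       exemplarsPerCategory = 3,
                       locations = c("left-up", "left-bottom",
                                     "right-up", "right-bottom"),
                       locationOffsets = NULL,
                       clutterLevels = c("no", "low", "high"),
                       nRuns = 20,
                       trialsPerConditionPerRun = 1) {
    if (is.null(locationOffsets)) {
        if (!identical(locations, c("left-up", "left-bottom",
                                    "right-up", "right-bottom")))
            stop("'locationOffsets' must be given for non-default locations")
        locationOffsets <- rbind(c(-3, 3), c(-3, -3), c(3, 3), c(3, -3))
    }
    locationOffsets <- as.matrix(locationOffsets)
    dimnames(locationOffsets) <- list(locations, c("h", "v"))
    new("DesignSpec",
        categories = as.character(categories),
        exemplarsPerCategory = as.integer(exemplarsPerCategory),
        locations = as.character(locations),
        locationOffsets = locationOffsets,
        clutterLevels = as.character(clutterLevels),
        nRuns = as.integer(nRuns),
        trialsPerConditionPerRun = as.integer(trialsPerConditionPerRun))
}

#' Enumerate the conditions of a crossed design
#'
#' Expands the full Cartesian product of the design factors in canonical
#' order: clutter varies slowest, then location, then category (and, at
#' exemplar level, exemplar fastest). The default design yields 48
#' category-level and 144 exemplar-level conditions. All condition axes in
#' the package (for example the condition dimension of an
#' [FMRIPatternSet-class]) follow this order, which is what lets
#' representational dissimilarity vectors align across modalities.
#'
#' @param design a [DesignSpec-class].
#' @param level \code{"category"} (default) or \code{"exemplar"}.
#'
#' @return A data.frame with columns \code{clutter}, \code{location},
#'   \code{category} (and \code{exemplar}), one row per condition.
#' @export
enumerateConditions <- function(design, level = c("category", "exemplar")) {
    level <- match.arg(level)
    validObject(design)
    if (level == "category") {
        out <- expand.grid(category = design@categories,
                           location = design@locations,
                           clutter = design@clutterLevels,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    } else {
        out <- expand.grid(exemplar = seq_len(design@exemplarsPerCategory),
                           category = design@categories,
                           location = design@locations,
                           clutter = design@clutterLevels,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    }
    # expand.grid varies its first factor fastest; reorder columns so the
    # canonical reading order (clutter slowest) is explicit
    out[, rev(seq_along(out)), drop = FALSE]
}

#' Build the pairwise cross-classification scheme
#'
#' Enumerates all unordered location pairs and all ordered (train, test)
#' category pairs of a design. With four locations and four categories
#' this gives the 6 pairwise location classifications and the 12 category
#' train/test iterations of the cross-decoding scheme. The
#' \code{cross_hemifield} and \code{within_hemifield} subsets keep only
#' location pairs that straddle, respectively stay inside, a hemifield
#' (horizontal offset sign), matched on elevation; the two diagonal pairs
#' belong only to \code{"all"}.
#'
#' @param design a [DesignSpec-class] with at least two locations and two
#'   categories.
#' @param subset \code{"all"} (default), \code{"cross_hemifield"} or
#'   \code{"within_hemifield"}.
#'
#' @return A [PairScheme-class].
#' @examples
#' sch <- buildPairScheme(designSpec())
#' nrow(locationPairs(sch))          # 6
#' nrow(categoryTrainTestPairs(sch)) # 12
#' @export
buildPairScheme <- function(design,
                            subset = c("all", "cross_hemifield",
                                       "within_hemifield")) {
    subset <- match.arg(subset)
    validObject(design)
    if (length(design@locations) < 2L || length(design@categories) < 2L)
        stop("cross-decoding needs at least 2 locations and 2 categories")
    lp <- t(utils::combn(design@locations, 2L))
    colnames(lp) <- c("locA", "locB")
    li <- t(utils::combn(seq_along(design@locations), 2L))
    lp <- .applySubset(lp, li, design@locationOffsets, subset)
    ctt <- .orderedPairs(design@categories)
    colnames(ctt) <- c("train", "test")
    new("PairScheme", locationPairs = lp,
        categoryTrainTestPairs = ctt, subset = subset)
}

.applySubset <- function(lp, li, offsets, subset) {
    if (subset == "all") return(lp)
    h <- sign(offsets[, "h"]); v <- sign(offsets[, "v"])
    keep <- switch(subset,
        cross_hemifield = h[li[, 1L]] != h[li[, 2L]] &
                          v[li[, 1L]] == v[li[, 2L]],
        within_hemifield = h[li[, 1L]] == h[li[, 2L]] &
                           v[li[, 1L]] != v[li[, 2L]])
    lp[keep, , drop = FALSE]
}

# All ordered pairs (a, b), a != b, grouped by unordered pair in canonical
# design order, direction a->b before b->a. This grouping defines the RDV
# entry order.
.orderedPairs <- function(x) {
    un <- t(utils::combn(x, 2L))
    out <- matrix(character(0), 0L, 2L)
    for (i in seq_len(nrow(un)))
        out <- rbind(out, un[i, ], rev(un[i, ]))
    out
}

#' Count the classification cells of a scheme
#'
#' The number of binary classification accuracies averaged into one
#' reported value: location pairs x ordered category train/test pairs x
#' randomization iterations. Under the default scheme this is 72 per
#' iteration and 7,200 at the 100 iterations used for time-resolved
#' decoding.
#'
#' @param scheme a [PairScheme-class].
#' @param nIterations number of randomization iterations (>= 1).
#'
#' @return Integer cell count.
#' @export
schemeCellCount <- function(scheme, nIterations = 1) {
    validObject(scheme)
    nIterations <- as.integer(nIterations)
    stopifnot(nIterations >= 1L)
    nrow(scheme@locationPairs) * nrow(scheme@categoryTrainTestPairs) *
        nIterations
}

#' Eccentricity of an object centre
#'
#' Euclidean distance of an object centre from the image centre, given
#' its signed horizontal and vertical offsets in degrees visual angle.
#' With the default quadrant offsets of 3 degrees from each midline the
#' objects sit 4.2 degrees from the image centre (displayed at one
#' decimal; the exact value is returned).
#'
#' @param offsetH,offsetV signed offsets in degrees visual angle.
#' @return Eccentricity in degrees (exact; round for display).
#' @examples
#' round(objectEccentricity(3, 3), 1)  # 4.2
#' @export
objectEccentricity <- function(offsetH, offsetV) {
    stopifnot(is.finite(offsetH), is.finite(offsetV))
    sqrt(offsetH^2 + offsetV^2)
}

#' Serialize a design specification to JSON
#'
#' @param design a [DesignSpec-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDesign <- function(design, path) {
    validObject(design)
    x <- list(categories = design@categories,
              exemplars_per_category = design@exemplarsPerCategory,
              locations = design@locations,
              offsets_deg = unname(apply(design@locationOffsets, 1L,
                                         function(r) as.numeric(r),
                                         simplify = FALSE)),
              clutter_levels = design@clutterLevels,
              n_runs = design@nRuns,
              trials_per_condition_per_run = design@trialsPerConditionPerRun)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a design specification from JSON
#'
#' @param path JSON file written by [writeDesign()].
#' @return A [DesignSpec-class].
#' @export
readDesign <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("categories", "exemplars_per_category", "locations",
              "offsets_deg", "clutter_levels", "n_runs",
              "trials_per_condition_per_run")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("design config is missing fields: ", paste(miss, collapse = ", "))
    off <- x$offsets_deg
    if (is.list(off)) off <- do.call(rbind, off)
    designSpec(categories = x$categories,
               exemplarsPerCategory = x$exemplars_per_category,
               locations = x$locations,
               locationOffsets = off,
               clutterLevels = x$clutter_levels,
               nRuns = x$n_runs,
               trialsPerConditionPerRun = x$trials_per_condition_per_run)
}
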