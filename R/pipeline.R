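#' Pipeline run configuration
#'
#' Bundles the generator configuration with the analysis parameters of
#' the end-to-end synthetic pipeline. Every stochastic stage derives its
#' seed deterministically from \code{rootSeed} and the stage name, so a
#' rerun with the same configuration reproduces every output byte for
#' byte.
#'
#' @param generator a [GeneratorConfig-class]; the default is a
#'   reduced-size configuration (16 channels at 100 Hz, 8 runs, two
#'   60-voxel ROIs) so that the full chain runs at desk scale.
#' @param nSubjects simulated subjects.
#' @param decode list: \code{nBins}, \code{roiBins}, \code{nIterations},
#'   \code{tempgenStepMs}, \code{tempgenWindow}, \code{peakWindow}.
#' @param searchlight list: \code{enabled}, \code{volumeRadius},
#'   \code{channelK}, \code{stepMs}.
#' @param stats list: \code{nBoot}, \code{q}.
#' @param rootSeed integer root seed.
#' @param outDir output directory.
#' @param verbose print one structured log line per stage.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(generator = NULL, nSubjects = 8,
                      decode = list(), searchlight = list(),
                      stats = list(), rootSeed = 1,
                      outDir = tempfile("mvpafuse_run"),
                      verbose = TRUE) {
    if (is.null(generator)) {
        fm <- .defaultFmri(c("no", "low", "high"))
        fm$rois$nVoxels <- c(60L, 60L)
        fm$gridShape <- c(8L, 8L, 4L)
        generator <- generatorConfig(
            design = designSpec(nRuns = 8),
            nChannels = 16, samplingRate = 100,
            epochWindow = c(-100, 490), fmri = fm)
    }
    decode <- utils::modifyList(
        list(nBins = 4L, roiBins = 5L, nIterations = 3L,
             tempgenStepMs = 50, tempgenWindow = c(-100, 450),
             peakWindow = c(0, 450)), decode)
    searchlight <- utils::modifyList(
        list(enabled = TRUE, volumeRadius = 2, channelK = 4,
             stepMs = 50), searchlight)
    stats <- utils::modifyList(list(nBoot = 1000L, q = 0.05), stats)
    validObject(generator)
    structure(list(generator = generator,
                   nSubjects = as.integer(nSubjects), decode = decode,
                   searchlight = searchlight, stats = stats,
                   rootSeed = as.integer(rootSeed), outDir = outDir,
                   verbose = isTRUE(verbose)),
              class = "RunConfig")
}

.logStage <- function(cfg, stage, seed, ...) {
    if (cfg$verbose)
        message(sprintf("[%s] seed=%d %s", stage, seed,
                        paste(..., sep = " ")))
}

#' Run the full synthetic decoding pipeline
#'
#' Chains every stage of the analysis on synthetic data: per-subject
#' generation (EEG, fMRI, features), multivariate noise normalization,
#' time-resolved, ROI-based and layer-wise cross-decoding for every
#' clutter level, voxel- and sensor-space searchlights, temporal
#' generalization from the first to the last clutter level with the
#' signed peak-to-diagonal statistic, EEG-fMRI RDV fusion at the group
#' EEG peak, and group statistics (Wilcoxon + FDR across time points,
#' bootstrap peak CIs and latency differences). All tabular results are
#' written as TSV under \code{config$outDir} together with a JSON
#' manifest listing every file with its generating stage and seed.
#'
#' @param config a [runConfig()] list.
#' @return Invisibly, a result bundle: \code{timecourses} (subject x
#'   time x clutter array), \code{roi}, \code{features}, \code{tempgen},
#'   \code{peakShifts}, \code{fusion}, \code{groupTests},
#'   \code{peakStats}, \code{manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    cfg <- config
    gen <- cfg$generator
    design <- gen@design
    clutters <- design@clutterLevels
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list()
    note <- function(file, stage, seed)
        manifest[[length(manifest) + 1L]] <<-
            list(file = basename(file), stage = stage, seed = seed)
    scheme <- buildPairScheme(design)
    seeds <- subjectSeeds(cfg$rootSeed, cfg$nSubjects)
    stage <- function(name) deriveSeed(cfg$rootSeed, name)

    tcFile <- file.path(cfg$outDir, "timecourse_accuracy.tsv")
    roiFile <- file.path(cfg$outDir, "roi_accuracy.tsv")
    featFile <- file.path(cfg$outDir, "feature_accuracy.tsv")
    for (f in c(tcFile, roiFile, featFile)) if (file.exists(f))
        file.remove(f)

    nT <- NULL
    timecourses <- NULL       # subject x time x clutter
    cellByTime <- list()      # per clutter: list over subjects
    roiRows <- list(); featRows <- list()
    fmriRDV <- list()         # [[clutter]][[roi]][[subject]]
    tgList <- list(); shifts <- numeric(0)
    slVol <- list(); slChan <- list()
    rois <- gen@fmri$rois$roi

    for (s in seq_len(cfg$nSubjects)) {
        sSeed <- seeds[s]
        .logStage(cfg, "simulate", sSeed, sprintf("subject=%d", s))
        eeg <- noiseNormalize(generateEEG(gen, seed = sSeed))
        fmri <- generateFMRI(gen, seed = deriveSeed(sSeed, "fmri"))
        feats <- generateFeatures(gen, seed = deriveSeed(sSeed, "features"))

        for (cl in clutters) {
            dSeed <- deriveSeed(sSeed, paste0("time-", cl))
            res <- crossDecodeTimecourse(eeg, "location", cl, scheme,
                                         nBins = cfg$decode$nBins,
                                         nIterations = cfg$decode$nIterations,
                                         seed = dSeed)
            if (is.null(timecourses)) {
                nT <- length(accuracy(res))
                timecourses <- array(
                    NA_real_, c(cfg$nSubjects, nT, length(clutters)),
                    dimnames = list(NULL, names(accuracy(res)), clutters))
            }
            timecourses[s, , cl] <- accuracy(res)
            cellByTime[[cl]] <- c(cellByTime[[cl]],
                                  list(cellAccuracy(res)))
            writeDecodingTSV(res, tcFile, subject = s,
                             modality = "eeg", seed = dSeed)

            for (roi in rois) {
                rSeed <- deriveSeed(sSeed, paste0("roi-", roi, "-", cl))
                rres <- crossDecodeROI(fmri, roi, "location", cl,
                                       scheme, nBins = cfg$decode$roiBins,
                                       seed = rSeed)
                roiRows[[length(roiRows) + 1L]] <-
                    data.frame(subject = s, roi = roi, clutter = cl,
                               accuracy = unname(accuracy(rres)))
                fmriRDV[[cl]][[roi]][[s]] <-
                    buildRDV(rres, modality = "fmri", tag = paste0("s", s))
                writeDecodingTSV(rres, roiFile, subject = s,
                                 modality = "fmri", seed = rSeed)
            }

            fSeed <- deriveSeed(sSeed, paste0("features-", cl))
            fres <- crossDecodeFeatures(feats, "location", cl, scheme,
                                        nBins = cfg$decode$nBins,
                                        nIterations = cfg$decode$nIterations,
                                        seed = fSeed)
            featRows[[length(featRows) + 1L]] <-
                data.frame(subject = s, layer = decodingIndex(fres),
                           clutter = cl,
                           accuracy = unname(accuracy(fres)))
            writeDecodingTSV(fres, featFile, subject = s,
                             modality = "features", seed = fSeed)
        }

        tgSeed <- deriveSeed(sSeed, "tempgen")
        tg <- temporalGeneralization(
            subsetEpochs(eeg, clutter = clutters[1L]),
            subsetEpochs(eeg, clutter = clutters[length(clutters)]),
            scheme = scheme, window = cfg$decode$tempgenWindow,
            stepMs = cfg$decode$tempgenStepMs,
            nBins = cfg$decode$nBins,
            nIterations = cfg$decode$nIterations, seed = tgSeed)
        tgList[[s]] <- tg
        shifts[s] <- peakToDiagonal(tg, cfg$decode$peakWindow)@dEuclidean

        if (isTRUE(cfg$searchlight$enabled)) {
            vSeed <- deriveSeed(sSeed, "searchlight-volume")
            slVol[[s]] <- searchlightVolume(
                fmri, "location", clutters[1L], scheme,
                radius = cfg$searchlight$volumeRadius,
                nBins = cfg$decode$roiBins, seed = vSeed)
            cSeed <- deriveSeed(sSeed, "searchlight-channels")
            slChan[[s]] <- searchlightChannels(
                eeg, "location", clutters[1L], scheme,
                k = cfg$searchlight$channelK,
                stepMs = cfg$searchlight$stepMs,
                nBins = cfg$decode$nBins, nIterations = 1,
                seed = cSeed)
        }
    }
    note(tcFile, "decode-time", stage("decode-time"))
    note(roiFile, "decode-roi", stage("decode-roi"))
    note(featFile, "decode-features", stage("decode-features"))

    timeMs <- as.numeric(dimnames(timecourses)[[2L]])
    # group stats: Wilcoxon + FDR across time, per clutter level
    groupTests <- do.call(rbind, lapply(clutters, function(cl) {
        wt <- do.call(rbind, lapply(seq_len(nT), function(t)
            wilcoxonVsChance(timecourses[, t, cl], 50)))
        fd <- fdrCorrect(wt$p, cfg$stats$q)
        data.frame(clutter = cl, timeMs = timeMs, p = wt$p,
                   pAdjusted = fd$pAdjusted,
                   significant = fd$significant)
    }))
    gtFile <- file.path(cfg$outDir, "group_timecourse_tests.tsv")
    utils::write.table(groupTests, gtFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(gtFile, "group-tests", stage("group-tests"))

    # peak latencies: bootstrap CI per clutter + pairwise differences
    bSeed <- stage("bootstrap")
    peakStats <- do.call(rbind, lapply(clutters, function(cl) {
        r <- bootstrapPeakCI(timecourses[, , cl], timeMs,
                             cfg$decode$peakWindow,
                             nBoot = cfg$stats$nBoot,
                             seed = deriveSeed(bSeed, cl))
        cbind(data.frame(clutter = cl), r)
    }))
    if (length(clutters) >= 2L) {
        prs <- utils::combn(clutters, 2L)
        diffs <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
            a <- prs[1L, i]; b <- prs[2L, i]
            r <- bootstrapDifference(timecourses[, , a],
                                     timecourses[, , b], timeMs,
                                     cfg$decode$peakWindow,
                                     nBoot = cfg$stats$nBoot,
                                     seed = deriveSeed(bSeed,
                                                       paste(a, b)))
            cbind(data.frame(clutter = paste(b, "-", a)), r)
        }))
        diffs$pAdjusted <- stats::p.adjust(diffs$p, method = "BH")
    } else diffs <- NULL
    psFile <- file.path(cfg$outDir, "peak_statistics.tsv")
    utils::write.table(peakStats, psFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(psFile, "bootstrap", bSeed)

    # peak shift across subjects (temporal generalization)
    shiftTest <- wilcoxonVsChance(shifts, 0)
    shiftTest$meanShiftMs <- mean(shifts)
    shiftTest$r <- signedRankEffectSize(shiftTest$z, length(shifts))

    # fusion: group EEG peak RDV x subject fMRI ROI RDVs
    fusion <- NULL
    entry <- .cellIndex(.schemeRoles(scheme, "location"))
    for (cl in clutters) {
        ci <- peakStats[peakStats$clutter == cl, ]
        eegR <- eegPeakRDV(cellByTime[[cl]], timeMs,
                           c(ci$ciLow, ci$ciHigh), entry,
                           clutter = cl)
        for (roi in rois) for (s in seq_len(cfg$nSubjects)) {
            rho <- fuseRDVs(eegR, fmriRDV[[cl]][[roi]][[s]])
            fusion <- rbind(fusion,
                            data.frame(subject = s, roi = roi,
                                       clutter = cl, rho = rho))
        }
    }
    fuFile <- file.path(cfg$outDir, "fusion_correlations.tsv")
    utils::write.table(fusion, fuFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(fuFile, "fusion", stage("fusion"))

    maniFile <- file.path(cfg$outDir, "manifest.json")
    jsonlite::write_json(
        list(rootSeed = cfg$rootSeed, nSubjects = cfg$nSubjects,
             outputs = manifest),
        maniFile, auto_unbox = TRUE, pretty = TRUE)

    invisible(list(timecourses = timecourses,
                   roi = do.call(rbind, roiRows),
                   features = do.call(rbind, featRows),
                   tempgen = tgList, peakShifts = shifts,
                   shiftTest = shiftTest, fusion = fusion,
                   groupTests = groupTests, peakStats = peakStats,
                   latencyDifferences = diffs,
                   searchlightVolumes = slVol,
                   searchlightChannelMaps = slChan,
                   manifest = manifest, outDir = cfg$outDir))
}
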