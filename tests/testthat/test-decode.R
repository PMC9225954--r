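test_that("full scheme accuracy matches exhaustive hand enumeration on a toy set", {
    # 2 categories x 2 locations, 2 identical trials per condition: with
    # 2 bins the pseudo-trials equal the raw patterns and the linear SVM
    # on one training point per class predicts by nearest training
    # pattern, so every cell can be enumerated by hand.
    set.seed(31)
    for (rep in 1:5) {
        pats <- list()
        for (cat in c("A", "B")) for (loc in c("left-up", "right-up"))
            pats[[paste(cat, loc, sep = "|")]] <- rnorm(3) * 2
        fs <- handFeatureSet(pats, reps = 2)
        sch <- twoByTwoScheme()
        res <- crossDecodeFeatures(fs, "location", "no", sch,
                                   nBins = 2, nIterations = 1, seed = rep)
        # hand enumeration over the 1 location pair x 2 ordered category
        # pairs, nearest-pattern prediction
        oracle <- mean(vapply(list(c("A", "B"), c("B", "A")),
                              function(tt) {
            trA <- pats[[paste(tt[1], "left-up", sep = "|")]]
            trB <- pats[[paste(tt[1], "right-up", sep = "|")]]
            teA <- pats[[paste(tt[2], "left-up", sep = "|")]]
            teB <- pats[[paste(tt[2], "right-up", sep = "|")]]
            nn <- function(x) ifelse(sum((x - trA)^2) < sum((x - trB)^2),
                                     "left-up", "right-up")
            mean(c(nn(teA) == "left-up", nn(teB) == "right-up")) * 100
        }, numeric(1)))
        expect_equal(unname(accuracy(res)), oracle)
        expect_equal(res@nCellsAveraged, 2L)
    }
})

test_that("reported accuracy is the mean of the per-cell accuracies", {
    d <- smallDesign(nRuns = 4, clutter = "no")
    cfg <- smallConfig(d, nChannels = 6, window = c(100, 190))
    ep <- generateEEG(cfg, seed = 51)
    res <- crossDecodeTimecourse(ep, "location", "no", nIterations = 2,
                                 seed = 5)
    expect_equal(unname(accuracy(res)),
                 unname(rowMeans(cellAccuracy(res))))
    expect_true(all(accuracy(res) >= 0 & accuracy(res) <= 100))
    expect_true(all(cellAccuracy(res) >= 0 & cellAccuracy(res) <= 100))
    expect_equal(res@nCellsAveraged, 144L)  # 72 cells x 2 iterations
})

test_that("swapping the class pair order leaves accuracies unchanged", {
    set.seed(32)
    pats <- list()
    for (cat in c("A", "B")) for (loc in c("left-up", "right-up"))
        pats[[paste(cat, loc, sep = "|")]] <- rnorm(4)
    fs <- handFeatureSet(pats, reps = 2)
    sch <- twoByTwoScheme()
    swapped <- new("PairScheme",
                   locationPairs = locationPairs(sch)[, 2:1,
                                                      drop = FALSE],
                   categoryTrainTestPairs = categoryTrainTestPairs(sch),
                   subset = "all")
    a <- accuracy(crossDecodeFeatures(fs, "location", "no", sch,
                                      nBins = 2, nIterations = 1,
                                      seed = 1))
    b <- accuracy(crossDecodeFeatures(fs, "location", "no", swapped,
                                      nBins = 2, nIterations = 1,
                                      seed = 1))
    expect_equal(unname(a), unname(b))
})

test_that("no-signal data decodes at chance", {
    d <- smallDesign(nRuns = 4, clutter = "no")
    cfg <- nullConfig(d, nChannels = 6, window = c(0, 50))
    ep <- generateEEG(cfg, seed = 61)
    res <- crossDecodeTimecourse(ep, "location", "no", nIterations = 3,
                                 seed = 6)
    expect_lt(abs(mean(accuracy(res)) - 50), 6)
})

test_that("ROI cross-validation has the expected fold structure and recovers the planted SNR gradient", {
    d <- designSpec()
    sch <- buildPairScheme(d)
    accs <- array(0, c(3, 2, 2),
                  dimnames = list(NULL, c("V1like", "LOClike"),
                                  c("no", "high")))
    for (s in 1:3) {
        fm <- generateFMRI(generatorConfig(d, fmri = tinyFmri(
            d@clutterLevels)), seed = 300 + s)
        for (roi in c("V1like", "LOClike")) for (cl in c("no", "high")) {
            r <- crossDecodeROI(fm, roi, "location", cl, sch, seed = s)
            expect_equal(r@nCellsAveraged, 360L)  # 72 cells x 5 folds
            accs[s, roi, cl] <- accuracy(r)
        }
    }
    m <- apply(accs, c(2, 3), mean)
    # planted: location SNR high in V1like only without clutter; the
    # LOClike signal is clutter-tolerant
    expect_gt(m["V1like", "no"], m["V1like", "high"] + 5)
    expect_lt(abs(m["V1like", "high"] - 50), 6)
    expect_gt(m["LOClike", "high"], 52)
})

test_that("run binning matches the pseudo-run contract", {
    d <- smallDesign(nRuns = 10, clutter = "no")
    fm <- generateFMRI(generatorConfig(d, fmri = tinyFmri("no")),
                       seed = 1)
    expect_equal(dim(patternData(fm))[1], 10L)
    r <- crossDecodeROI(fm, "V1like", "location", "no", nBins = 5,
                        seed = 2)
    expect_equal(r@nCellsAveraged, 360L)
    expect_error(crossDecodeROI(fm, "V1like", "location", "no",
                                nBins = 11, seed = 2),
                 "infeasible binning")
    expect_error(crossDecodeROI(fm, "nonexistent", "location", "no",
                                seed = 2), "ROI not present")
})

test_that("layer-wise decoding recovers planted separability ordering", {
    d <- designSpec(nRuns = 6)
    layers <- paste0("layer", 1:4)
    sep <- matrix(0, 4, 3, dimnames = list(layers, d@clutterLevels))
    sep[, "high"] <- c(0.1, 0.5, 1, 2)
    cfg <- generatorConfig(d, features = list(
        layerNames = layers, nUnits = 64,
        sepLocation = sep,
        sepCategory = matrix(0.3, 4, 3,
                             dimnames = list(layers, d@clutterLevels))))
    accs <- sapply(1:3, function(s) {
        ft <- generateFeatures(cfg, seed = 400 + s)
        accuracy(crossDecodeFeatures(ft, "location", "high",
                                     nIterations = 2, seed = s))
    })
    m <- rowMeans(accs)
    expect_gt(m["layer4"], m["layer1"] + 3)
    expect_gt(stats::cor(m, 1:4, method = "spearman"), 0.7)
})

test_that("category is decodable across locations when planted", {
    d <- smallDesign(nRuns = 5, clutter = "no")
    cfg <- smallConfig(d, nChannels = 10, window = c(180, 250),
                       locAmplitude = 0, catAmplitude = 2,
                       catLatency = 215)
    ep <- generateEEG(cfg, seed = 71)
    res <- crossDecodeTimecourse(ep, "category", "no", nIterations = 2,
                                 seed = 7)
    tLat <- which.min(abs(as.numeric(decodingIndex(res)) - 215))
    expect_gt(accuracy(res)[tLat], 60)
})

test_that("top-k voxel selection is deterministic with documented ties", {
    stat <- c(5, 1, 5, 3, 2)
    mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
    expect_equal(selectTopKVoxels(stat, mask, 3), c(1L, 3L, 4L))
    # min selected >= max excluded
    sel <- selectTopKVoxels(stat, mask, 2)
    expect_gte(min(stat[sel]), max(stat[setdiff(which(mask), sel)]))
    # constant map: first k in coordinate order
    expect_equal(selectTopKVoxels(rep(1, 6), rep(TRUE, 6), 3), 1:3)
    expect_equal(selectTopKVoxels(stat, mask, 4), c(1L, 3L, 4L, 2L))
    expect_error(selectTopKVoxels(stat, mask, 5),
                 "infeasible selection")
})
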