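test_that("sphere membership matches brute-force lattice counts", {
    # independent oracle: triple loop over the cube
    bruteCount <- function(r) {
        n <- 0L
        for (x in -r:r) for (y in -r:r) for (z in -r:r)
            if (x * x + y * y + z * z <= r * r) n <- n + 1L
        n
    }
    counts <- vapply(1:5, function(r) nrow(sphereOffsets(r)), integer(1))
    expect_equal(counts, vapply(1:5, bruteCount, integer(1)))
    expect_equal(counts, c(7L, 33L, 123L, 257L, 515L))
    # symmetry: offsets closed under negation
    off <- sphereOffsets(3)
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    expect_equal(key(off), key(-off))
})

test_that("radius-0 searchlight equals voxel-wise decoding", {
    d <- smallDesign(nRuns = 6, clutter = "no")
    fm <- generateFMRI(generatorConfig(d, fmri = tinyFmri(
        "no", nVoxels = c(6L, 6L), grid = c(4L, 3L, 2L))), seed = 5)
    sl <- searchlightVolume(fm, "location", "no", radius = 0, seed = 9,
                            centers = 1:3)
    for (v in 1:3) {
        direct <- crossDecodeROI(fm, voxels = v, target = "location",
                                 clutter = "no", seed = 9)
        expect_equal(accuracy(sl)[v], unname(accuracy(direct)))
    }
    expect_true(all(is.na(accuracy(sl)[4:12])))
})

test_that("volumetric searchlight localizes a planted signal block", {
    d <- smallDesign(nRuns = 6, clutter = "no")
    # signal only in the first ROI block of the grid
    fm <- tinyFmri("no", nVoxels = c(12L, 20L), grid = c(4L, 4L, 2L))
    fm$snrLocation["V1like", ] <- 4
    fm$snrLocation["LOClike", ] <- 0
    maps <- sapply(1:2, function(s) {
        pat <- generateFMRI(generatorConfig(d, fmri = fm), seed = 500 + s)
        accuracy(searchlightVolume(pat, "location", "no", radius = 1,
                                   seed = s))
    })
    # the group-mean peak falls inside the signal block (voxels 1..12)
    expect_lte(which.max(rowMeans(maps)), 12L)
})

test_that("channel searchlight uses k neighbors and finds informative channels", {
    d <- smallDesign(nRuns = 4, clutter = "no")
    cfg <- smallConfig(d, nChannels = 8, window = c(100, 190),
                       locLatency = 140, locAmplitude = 2)
    ep <- generateEEG(cfg, seed = 15)
    sc <- searchlightChannels(ep, "location", "no", k = 3, stepMs = 30,
                              nIterations = 1, seed = 3)
    expect_equal(dim(accuracy(sc)), c(8L, 3L))
    expect_equal(sc@neighborhoodSize, 3L)
    expect_true(all(accuracy(sc) >= 0 & accuracy(sc) <= 100))
    expect_error(searchlightChannels(ep, "location", "no", k = 8,
                                     seed = 1), "smaller than")
})

test_that("time down-sampling averages non-overlapping bins", {
    # ramp oracle: 0..99 in 10-bins -> 4.5, 14.5, ...
    r <- downsampleTime(as.numeric(0:99), stepMs = 10,
                        timeMs = as.numeric(0:99))
    expect_equal(unname(r$values), seq(4.5, 94.5, by = 10))
    expect_equal(length(r$values), 10L)
    # constant course unchanged
    cst <- downsampleTime(rep(7, 40), stepMs = 4,
                          timeMs = as.numeric(1:40))
    expect_true(all(cst$values == 7))
    # 1 kHz epoch tensor: length divided by 10
    d <- smallDesign(nRuns = 1, clutter = "no", exemplars = 1)
    cfg <- smallConfig(d, nChannels = 4, samplingRate = 1000,
                       window = c(-100, 99),
                       locLatency = 50, catLatency = 50)
    ep <- generateEEG(cfg, seed = 2)
    ds <- downsampleTime(ep, 10)
    expect_equal(dim(epochData(ds))[3], 20L)
    expect_equal(epochData(ds)[1, 1, 1],
                 mean(epochData(ep)[1, 1, 1:10]))
    expect_error(downsampleTime(ep, 0.5), "smaller than native")
})

test_that("temporal generalization diagonal matches time-resolved decoding", {
    d <- smallDesign(nRuns = 5, clutter = "no")
    cfg <- smallConfig(d, nChannels = 10, window = c(-100, 290),
                       locLatency = 140, locAmplitude = 2)
    ep <- noiseNormalize(generateEEG(cfg, seed = 25))
    tg <- temporalGeneralization(ep, ep, scheme = NULL,
                                 window = c(-100, 250), stepMs = 50,
                                 nIterations = 4, seed = 4)
    expect_equal(dim(accuracy(tg)), c(8L, 8L))
    tc <- crossDecodeTimecourse(ep, "location", "no", nIterations = 4,
                                seed = 4)
    grid <- trainTimes(tg)
    tcOnGrid <- accuracy(tc)[match(grid, as.numeric(decodingIndex(tc)))]
    expect_lt(max(abs(diag(accuracy(tg)) - tcOnGrid)), 8)
    expect_gt(stats::cor(diag(accuracy(tg)), tcOnGrid), 0.8)
})

test_that("default grid spans 71 points at 10 ms steps", {
    expect_equal(length(seq(-100, 600, by = 10)), 71L)
    d <- smallDesign(nRuns = 4, clutter = "no")
    cfg <- smallConfig(d, nChannels = 4, window = c(-100, 90),
                       locLatency = 50, catLatency = 50)
    ep <- generateEEG(cfg, seed = 3)
    expect_error(temporalGeneralization(ep, ep, window = c(-100, 600),
                                        stepMs = 10, seed = 1),
                 "window outside")
    expect_error(temporalGeneralization(ep, ep, window = c(-100, 80),
                                        stepMs = 1, seed = 1),
                 "finer than the native")
})

test_that("peak-to-diagonal statistics reproduce the closed-form values", {
    mk <- function(peakTrain, peakTest) {
        ax <- seq(0, 400, by = 100)
        m <- matrix(50, 5, 5, dimnames = list(ax, ax))
        m[match(peakTrain, ax), match(peakTest, ax)] <- 90
        new("GeneralizationMatrix", accuracy = m, trainAxisMs = ax,
            testAxisMs = ax, trainCondition = "no",
            testCondition = "high", target = "location")
    }
    # peak at train 100 ms (y), test 300 ms (x): below the diagonal
    ps <- peakToDiagonal(mk(100, 300), c(0, 400))
    expect_equal(ps@pX, 300)
    expect_equal(ps@pY, 100)
    expect_equal(ps@bX, 200)
    expect_equal(ps@dEuclidean, sqrt(2) * 100, tolerance = 1e-12)
    expect_equal(round(ps@dEuclidean, 2), 141.42)
    # mirrored peak: sign flips
    ps2 <- peakToDiagonal(mk(300, 100), c(0, 400))
    expect_equal(ps2@dEuclidean, -sqrt(2) * 100, tolerance = 1e-12)
    # on-diagonal peak: zero distance
    ps3 <- peakToDiagonal(mk(200, 200), c(0, 400))
    expect_equal(ps3@dEuclidean, 0)
    # closed form: k grid steps off the diagonal -> k * step / sqrt(2)
    for (k in 1:3) {
        ps4 <- peakToDiagonal(mk(0, k * 100), c(0, 400))
        expect_equal(ps4@dEuclidean, k * 100 / sqrt(2),
                     tolerance = 1e-12)
    }
    # ties resolved toward the diagonal and flagged
    ax <- seq(0, 400, by = 100)
    m <- matrix(50, 5, 5); m[1, 3] <- 90; m[2, 3] <- 90
    gm <- new("GeneralizationMatrix", accuracy = m, trainAxisMs = ax,
              testAxisMs = ax, trainCondition = "no",
              testCondition = "high", target = "location")
    ps5 <- peakToDiagonal(gm, c(0, 400))
    expect_true(ps5@tied)
    expect_equal(ps5@pY, 100)  # closer to the diagonal than train 0
})

test_that("diagonal difference is exactly antisymmetric", {
    ax <- seq(0, 300, by = 100)
    set.seed(8)
    m <- matrix(runif(16, 40, 60), 4, 4)
    gm <- new("GeneralizationMatrix", accuracy = m, trainAxisMs = ax,
              testAxisMs = ax, trainCondition = "no",
              testCondition = "high", target = "location")
    dd <- diagonalDifference(gm)
    expect_equal(dd + t(dd), matrix(0, 4, 4), ignore_attr = TRUE)
    expect_equal(diag(dd), rep(0, 4))
    expect_equal(dd[3, 1], m[3, 1] - m[1, 3])
    # symmetric input -> all zeros
    gs <- new("GeneralizationMatrix", accuracy = (m + t(m)) / 2,
              trainAxisMs = ax, testAxisMs = ax, trainCondition = "no",
              testCondition = "high", target = "location")
    expect_true(all(diagonalDifference(gs) == 0))
})

test_that("peak latency search honors window, ties and boundaries", {
    tm <- seq(0, 500, by = 10)
    bump <- exp(-(tm - 300)^2 / 2000)
    expect_equal(findPeakLatency(bump, tm, c(0, 500)), 300)
    # monotone course peaks at the window edge
    expect_equal(findPeakLatency(as.numeric(tm), tm, c(0, 400)), 400)
    # ties break to the earliest time point
    flat <- rep(1, length(tm))
    expect_equal(findPeakLatency(flat, tm, c(100, 400)), 100)
    expect_error(findPeakLatency(bump, tm, c(600, 700)), "empty")
})
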