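test_that("RDVs have the canonical length and stable order", {
    d <- designSpec()
    sch <- buildPairScheme(d)
    roles <- mvpaFuse:::.schemeRoles(sch, "location")
    entry <- mvpaFuse:::.cellIndex(roles)
    expect_equal(nrow(entry), 72L)
    # 6 location pairs x 6 unordered category pairs x 2 directions
    expect_equal(length(unique(paste(entry$classA, entry$classB))), 6L)
    dirKey <- paste(pmin(entry$train, entry$test),
                    pmax(entry$train, entry$test))
    expect_equal(length(unique(dirKey)), 6L)

    set.seed(2)
    tab <- entry
    tab$accuracy <- runif(72, 40, 90)
    shuffled <- tab[sample.int(72), ]
    r1 <- buildRDV(shuffled, sch, modality = "fmri")
    r2 <- buildRDV(shuffled, sch, modality = "fmri")
    expect_equal(rdvValues(r1), tab$accuracy)   # canonical reordering
    expect_identical(rdvValues(r1), rdvValues(r2))
    expect_error(buildRDV(tab[-5, ], sch), "incomplete RDV")

    two <- twoByTwoScheme()
    tiny <- mvpaFuse:::.cellIndex(mvpaFuse:::.schemeRoles(two, "location"))
    tiny$accuracy <- c(60, 70)
    expect_length(rdvValues(buildRDV(tiny, two)), 2L)
})

test_that("fusion is a rank correlation with monotone invariance", {
    d <- designSpec()
    sch <- buildPairScheme(d)
    entry <- mvpaFuse:::.cellIndex(mvpaFuse:::.schemeRoles(sch, "location"))
    set.seed(3)
    v <- runif(72, 40, 90)
    mk <- function(x) new("RDV", values = x, entryIndex = entry,
                          modality = "m", clutter = "no", tag = "")
    expect_equal(fuseRDVs(mk(v), mk(v)), 1)
    # exactly reversed ranks -> -1
    expect_equal(fuseRDVs(mk(v), mk(100 - v)), -1)
    # strictly monotone transform leaves the correlation unchanged
    w <- runif(72, 40, 90)
    expect_equal(fuseRDVs(mk(v), mk(w)),
                 fuseRDVs(mk(exp(v / 10)), mk(w^3)))
    expect_error(fuseRDVs(mk(rep(50, 72)), mk(v)),
                 "undefined correlation")
    entry2 <- entry[c(2, 1, 3:72), ]
    expect_error(fuseRDVs(mk(v),
                          new("RDV", values = v, entryIndex = entry2,
                              modality = "m", clutter = "no",
                              tag = "")),
                 "entry orders differ")
})

test_that("peak-window RDV averaging collapses time then subjects", {
    entry <- data.frame(classA = "x", classB = "y", train = "a",
                        test = "b")[rep(1, 4), ]
    tm <- c(100, 110, 120, 130)
    s1 <- matrix(rep(c(60, 80, 70, 0), each = 4), 4, byrow = FALSE)
    # single subject, single time point: identity
    r <- eegPeakRDV(list(s1), tm, c(110, 110), entry)
    expect_equal(rdvValues(r), s1[2, ])
    # two subjects v and 100 - v average to a constant 50
    v <- matrix(runif(4 * 4, 0, 100), 4)
    r2 <- eegPeakRDV(list(v, 100 - v), tm, c(100, 130), entry)
    expect_equal(rdvValues(r2), rep(50, 4))
    expect_error(eegPeakRDV(list(v), tm, c(500, 600), entry), "empty")
})

test_that("signed-rank test matches exact small-sample behavior", {
    # symmetric values around the null -> p ~ 1
    sym <- 50 + c(-3, -2, -1, 1, 2, 3)
    expect_gt(wilcoxonVsChance(sym, 50)$p, 0.8)
    # all 25 values above the null: smallest attainable two-tailed p
    set.seed(4)
    above <- 55 + runif(25)
    r <- wilcoxonVsChance(above, 50)
    expect_equal(r$p, 2 * (1 / 2)^25, tolerance = 1e-10)
    expect_equal(r$n, 25L)
    # degenerate: all differences zero
    r0 <- wilcoxonVsChance(rep(50, 8), 50)
    expect_true(r0$degenerate)
    # planted above-chance effect has high power at n = 20
    set.seed(5)
    hits <- vapply(1:60, function(i)
        wilcoxonVsChance(rnorm(20, 53, 3), 50)$p < 0.05, logical(1))
    expect_gt(mean(hits), 0.9)
})

test_that("BH decisions equal the brute-force step-up oracle", {
    stepUpOracle <- function(p, q) {
        m <- length(p)
        o <- order(p)
        ps <- p[o]
        k <- 0
        for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
        rej <- rep(FALSE, m)
        if (k > 0) rej[o[seq_len(k)]] <- TRUE
        rej
    }
    set.seed(6)
    for (len in c(1:8)) {
        for (rep in 1:25) {
            p <- round(runif(len), 2)
            expect_identical(fdrCorrect(p, 0.05)$significant,
                             stepUpOracle(p, 0.05))
        }
    }
    expect_true(all(fdrCorrect(rep(0.01, 7))$significant))
    expect_identical(fdrCorrect(0.04)$significant, TRUE)
    expect_identical(fdrCorrect(0.06)$significant, FALSE)
    # the step-up for (0.01, 0.02, 0.04, 0.2): p(3) = 0.04 > 3*0.05/4,
    # so exactly the first two are rejected
    expect_identical(fdrCorrect(c(0.01, 0.02, 0.04, 0.2))$significant,
                     c(TRUE, TRUE, FALSE, FALSE))
})

test_that("effect sizes follow their defining formulas", {
    expect_equal(partialEtaSquared(30, 70), 0.3)
    expect_equal(partialEtaSquared(5, 0), 1)
    expect_equal(partialEtaSquared(0, 5), 0)
    expect_error(partialEtaSquared(0, 0), "undefined")
    expect_equal(signedRankEffectSize(0, 20), 0)
    # inverse of the printed r = 0.65 at N = 27
    expect_equal(signedRankEffectSize(0.65 * sqrt(27), 27), 0.65)
    expect_equal(signedRankEffectSize(2, 16), 0.5)
    expect_equal(signedRankEffectSize(2, 4) / signedRankEffectSize(2, 16),
                 2)
})

test_that("peak bootstraps are reproducible with sensible intervals", {
    tm <- seq(0, 400, by = 20)
    bump <- function(lat) exp(-(tm - lat)^2 / 4000) * 10 + 50
    # identical subjects: zero-width CI at the true peak
    same <- matrix(rep(bump(200), 6), 6, byrow = TRUE)
    r <- bootstrapPeakCI(same, tm, c(0, 400), nBoot = 200, seed = 1)
    expect_equal(c(r$estimate, r$ciLow, r$ciHigh), c(200, 200, 200))
    # determinism under a fixed seed
    set.seed(7)
    noisy <- t(vapply(1:10, function(i)
        bump(200) + rnorm(length(tm)), numeric(length(tm))))
    r1 <- bootstrapPeakCI(noisy, tm, c(0, 400), nBoot = 300, seed = 2)
    r2 <- bootstrapPeakCI(noisy, tm, c(0, 400), nBoot = 300, seed = 2)
    expect_identical(r1, r2)
    expect_true(r1$ciLow <= r1$estimate && r1$estimate <= r1$ciHigh)
})

test_that("paired latency-difference bootstrap has the right sign convention", {
    tm <- seq(0, 400, by = 20)
    bump <- function(lat) exp(-(tm - lat)^2 / 3000) * 10 + 50
    set.seed(8)
    early <- t(vapply(1:12, function(i) bump(120) + rnorm(length(tm), 0,
                                                          0.5),
                      numeric(length(tm))))
    late <- t(vapply(1:12, function(i) bump(280) + rnorm(length(tm), 0,
                                                         0.5),
                     numeric(length(tm))))
    # B later than A: difference positive, p small
    r <- bootstrapDifference(early, late, tm, c(0, 400), nBoot = 400,
                             seed = 3)
    expect_gt(r$estimate, 100)
    expect_lt(r$p, 0.05)
    # A later than B: p near 1 (direction check)
    r2 <- bootstrapDifference(late, early, tm, c(0, 400), nBoot = 400,
                              seed = 3)
    expect_gt(r2$p, 0.95)
    # A = B: difference distribution symmetric about zero
    r3 <- bootstrapDifference(early, early, tm, c(0, 400), nBoot = 400,
                              seed = 4)
    expect_equal(r3$estimate, 0)
    expect_gt(r3$p, 0.2)
})

test_that("searchlight peak-distance null behaves under exchange", {
    coords <- as.matrix(expand.grid(0:3, 0:3, 0:1))
    set.seed(9)
    peakMap <- function(peakVox) {
        base <- rnorm(nrow(coords), 50, 0.5)
        base[peakVox] <- base[peakVox] + 10
        base
    }
    A <- t(vapply(1:8, function(i) peakMap(3), numeric(nrow(coords))))
    B <- t(vapply(1:8, function(i) peakMap(30), numeric(nrow(coords))))
    r <- bootstrapSearchlightPeakDistance(A, B, coords, nBoot = 300,
                                          seed = 5)
    # observed statistic recovers the planted peak separation
    expect_equal(r$estimate,
                 sqrt(sum((coords[3, ] - coords[30, ])^2)))
    # identical maps: distance 0, p ~ 1
    r2 <- bootstrapSearchlightPeakDistance(A, A, coords, nBoot = 300,
                                           seed = 6)
    expect_equal(r2$estimate, 0)
    expect_gt(r2$p, 0.95)
    # globally relabeling both conditions leaves the null invariant
    r3 <- bootstrapSearchlightPeakDistance(B, A, coords, nBoot = 300,
                                           seed = 5)
    expect_equal(r3$estimate, r$estimate)
    expect_identical(r3$p, r$p)
    # reproducible under a fixed seed
    expect_identical(r, bootstrapSearchlightPeakDistance(
        A, B, coords, nBoot = 300, seed = 5))
})

test_that("null experiments keep the FDR-significant fraction controlled", {
    # type-I control of the Wilcoxon + FDR stack over simulated null
    # experiments (20 subjects x 30 time points of chance accuracies)
    set.seed(10)
    frac <- vapply(1:200, function(e) {
        acc <- matrix(rnorm(20 * 30, 50, 2), 20, 30)
        p <- vapply(seq_len(30), function(t)
            wilcoxonVsChance(acc[, t], 50)$p, numeric(1))
        mean(fdrCorrect(p, 0.05)$significant)
    }, numeric(1))
    expect_lte(mean(frac), 0.05 + 0.02)
})
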