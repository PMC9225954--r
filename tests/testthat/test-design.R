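test_that("condition enumeration matches the crossed design", {
    d <- designSpec()
    cat48 <- enumerateConditions(d, "category")
    ex144 <- enumerateConditions(d, "exemplar")
    expect_equal(nrow(cat48), 48L)
    expect_equal(nrow(ex144), 144L)
    expect_equal(nrow(ex144), nrow(cat48) * d@exemplarsPerCategory)

    # canonical order: clutter slowest, then location, then category
    expect_equal(cat48$clutter, rep(c("no", "low", "high"), each = 16))
    expect_equal(cat48$location[1:8],
                 rep(c("left-up", "left-bottom"), each = 4))
    expect_equal(cat48$category[1:4],
                 c("animals", "cars", "faces", "chairs"))

    # order is a pure function of the design
    expect_identical(cat48, enumerateConditions(designSpec(), "category"))

    one <- designSpec(categories = "a", exemplarsPerCategory = 1,
                      locations = "left-up",
                      locationOffsets = rbind(c(-3, 3)),
                      clutterLevels = "no", nRuns = 1,
                      trialsPerConditionPerRun = 1)
    expect_equal(nrow(enumerateConditions(one)), 1L)
    expect_error(designSpec(clutterLevels = character(0)), "non-empty")
    expect_error(designSpec(categories = c("a", "a", "b", "c")),
                 "duplicate")
})

test_that("pair schemes enumerate the cross-classification cells", {
    d <- designSpec()
    sch <- buildPairScheme(d)
    expect_equal(nrow(locationPairs(sch)), 6L)
    expect_equal(nrow(categoryTrainTestPairs(sch)), 12L)
    expect_true(all(categoryTrainTestPairs(sch)[, 1] !=
                    categoryTrainTestPairs(sch)[, 2]))
    expect_equal(schemeCellCount(sch), 72L)
    expect_equal(schemeCellCount(sch, 100), 7200L)
    expect_equal(schemeCellCount(sch, 1) * 5, 360L)

    two <- twoByTwoScheme()
    expect_equal(nrow(locationPairs(two)), 1L)
    expect_equal(nrow(categoryTrainTestPairs(two)), 2L)
    expect_equal(schemeCellCount(two), 2L)

    # counts against brute-force enumeration for k, m <= 6
    for (k in 2:6) for (m in 2:6) {
        locs <- paste0("L", seq_len(k))
        cats <- paste0("C", seq_len(m))
        dd <- designSpec(categories = cats, exemplarsPerCategory = 1,
                         locations = locs,
                         locationOffsets = cbind(seq_len(k), 1),
                         clutterLevels = "no", nRuns = 1,
                         trialsPerConditionPerRun = 1)
        s <- buildPairScheme(dd)
        bruteLoc <- sum(outer(seq_len(k), seq_len(k), "<"))
        bruteCat <- sum(outer(seq_len(m), seq_len(m), "!="))
        expect_equal(nrow(locationPairs(s)), bruteLoc)
        expect_equal(nrow(categoryTrainTestPairs(s)), bruteCat)
    }
})

test_that("hemifield subsets are disjoint, named and exclude diagonals", {
    d <- designSpec()
    all6 <- locationPairs(buildPairScheme(d, "all"))
    cross <- locationPairs(buildPairScheme(d, "cross_hemifield"))
    within <- locationPairs(buildPairScheme(d, "within_hemifield"))
    key <- function(m) apply(m, 1, function(r) paste(sort(r),
                                                     collapse = "|"))
    expect_equal(nrow(cross), 2L)
    expect_equal(nrow(within), 2L)
    expect_setequal(key(cross),
                    c("left-up|right-up", "left-bottom|right-bottom"))
    expect_setequal(key(within),
                    c("left-bottom|left-up", "right-bottom|right-up"))
    expect_length(intersect(key(cross), key(within)), 0L)
    expect_true(all(c(key(cross), key(within)) %in% key(all6)))
    expect_length(setdiff(key(all6), c(key(cross), key(within))), 2L)
})

test_that("object eccentricity is the exact Euclidean norm", {
    expect_equal(round(objectEccentricity(3, 3), 1), 4.2)
    expect_equal(objectEccentricity(3, 3), sqrt(18))
    expect_equal(objectEccentricity(0, 0), 0)
    expect_equal(objectEccentricity(3, 4), 5)
})

test_that("design specs round-trip through JSON", {
    d <- designSpec(nRuns = 7, trialsPerConditionPerRun = 2)
    path <- tempfile(fileext = ".json")
    writeDesign(d, path)
    d2 <- readDesign(path)
    expect_equal(d2@categories, d@categories)
    expect_equal(d2@locationOffsets, d@locationOffsets)
    expect_equal(d2@nRuns, d@nRuns)
    expect_equal(d2@trialsPerConditionPerRun, 2L)

    bad <- tempfile(fileext = ".json")
    jsonlite::write_json(list(categories = c("a", "b")), bad)
    expect_error(readDesign(bad), "missing fields")
})
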