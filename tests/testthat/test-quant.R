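test_that("scoped totals sum slices and replicates, matching brute force", {
    x <- toyExperiment(list(WT_1 = matrix(c(1, 2, 3), 1, 3,
                                          dimnames = list("P1"))))
    expect_equal(totalAbundance(x, "WT", "P1"), 6)
    y <- toyExperiment(list(
        WT_1 = matrix(c(0, 2, 0), 1, 3, dimnames = list("P1")),
        WT_2 = matrix(c(0, 4, 0), 1, 3, dimnames = list("P1"))))
    bm <- bandMap(list(mid = 2))
    expect_equal(totalAbundance(y, "WT", "P1", "mid", bm), 6)
    expect_error(totalAbundance(y, "WT", "P1", "nope", bm), "unknown band")
    expect_error(totalAbundance(y, "WT", "P1", "mid"), "BandMap")
    # random matrix, random band: brute-force triple loop
    cube <- randomCube(4, 6, c("WT_1", "WT_2", "MUT_1"), seed = 17)
    x <- toyExperiment(list(WT_1 = cube[, , 1], WT_2 = cube[, , 2],
                            MUT_1 = cube[, , 3]))
    bm <- bandMap(list(b = c(3, 4)))
    for (p in rownames(x)) {
        brute <- 0
        for (k in 3:4) for (s in c("WT_1", "WT_2"))
            brute <- brute + cube[p, k, s]
        expect_equal(totalAbundance(x, "WT", p, "b", bm), brute)
    }
})

test_that("ratio median uses the even-n convention and excludes nd", {
    expect_equal(ratioMedian(c(1.27, 1.30, 1.28, 1.08, 1.52, 1.52, 1.28,
                               1.72)), 1.29)
    expect_equal(ratioMedian(c(4.84, 4.81, 5.60, 6.05, 6.55, 9.67, 6.28)),
                 6.05)
    expect_equal(ratioMedian(5.5), 5.5)
    expect_equal(ratioMedian(c(2, NA, 4)), 3)
    expect_error(ratioMedian(c(NA_real_, NA_real_)), "no defined")
})

test_that("complex ratio tables form b/a ratios with nd handling", {
    # all members exactly halved in the test group
    mk <- function(v) matrix(v, 3, 2, byrow = FALSE,
                             dimnames = list(c("S1", "S2", "S3")))
    x <- toyExperiment(list(WT_1 = mk(c(2, 4, 6)), MUT_1 = mk(c(1, 2, 3))),
                       group = c("WT", "MUT"), replicate = c(1, 1))
    cat <- complexCatalog(data.frame(complex = "C",
                                     protein = c("S1", "S2", "S3"),
                                     subunit_class = "core"))
    tab <- complexRatioTable(x, cat, "C", "WT", "MUT")
    expect_equal(tab$entries$ratio, rep(0.5, 3))
    expect_equal(tab$median_ratio, 0.5)
    # member zero in the reference -> nd, excluded from the median
    z <- mk(c(0, 4, 6)); z["S1", ] <- 0
    xz <- toyExperiment(list(WT_1 = z, MUT_1 = mk(c(1, 2, 3))),
                        group = c("WT", "MUT"), replicate = c(1, 1))
    tz <- complexRatioTable(xz, cat, "C", "WT", "MUT")
    expect_true(is.na(tz$entries$ratio[tz$entries$protein == "S1"]))
    expect_equal(tz$median_ratio,
                 ratioMedian(tz$entries$ratio[-1]))
    # hand-set 5-member complex
    totals_a <- c(10, 20, 30, 40, 50); totals_b <- c(5, 30, 30, 10, 100)
    m5 <- function(v) matrix(v, 5, 1, dimnames = list(sprintf("M%d", 1:5)))
    x5 <- toyExperiment(list(WT_1 = m5(totals_a), MUT_1 = m5(totals_b)),
                        group = c("WT", "MUT"), replicate = c(1, 1))
    cat5 <- complexCatalog(data.frame(complex = "C",
                                      protein = sprintf("M%d", 1:5),
                                      subunit_class = "core"))
    t5 <- complexRatioTable(x5, cat5, "C", "WT", "MUT")
    expect_equal(t5$entries$ratio, totals_b / totals_a)
    expect_equal(t5$median_ratio, median(totals_b / totals_a))
    # absent member is reported and skipped
    cat6 <- complexCatalog(data.frame(complex = "C",
                                      protein = c(sprintf("M%d", 1:5), "GHOST"),
                                      subunit_class = "core"))
    t6 <- complexRatioTable(x5, cat6, "C", "WT", "MUT")
    expect_identical(t6$absent, "GHOST")
    expect_equal(nrow(t6$entries), 5L)
    # nothing detected in either group -> NA median with warning
    x0 <- toyExperiment(list(WT_1 = m5(rep(0, 5)), MUT_1 = m5(rep(0, 5))),
                        group = c("WT", "MUT"), replicate = c(1, 1))
    expect_warning(t0 <- complexRatioTable(x0, cat5, "C", "WT", "MUT"),
                   "no member detected")
    expect_true(is.na(t0$median_ratio))
})

test_that("band panels isolate bands; single members; nd stays band-local", {
    S <- 6
    mk <- function(v) matrix(v, 2, S, byrow = TRUE,
                             dimnames = list(c("A", "B")))
    wt <- mk(c(1, 0, 2, 0, 3, 0)); wt["B", 3] <- 0   # B absent from band b2
    mut <- mk(c(2, 0, 4, 0, 3, 0)); mut["B", 3] <- 0
    x <- toyExperiment(list(WT_1 = wt, MUT_1 = mut),
                       group = c("WT", "MUT"), replicate = c(1, 1))
    bm <- bandMap(list(b1 = 1, b2 = 3, b3 = 5))
    cat <- complexCatalog(data.frame(complex = "C", protein = c("A", "B"),
                                     subunit_class = "core"))
    pan <- bandRatioPanel(x, cat, "C", "WT", "MUT", bm)
    expect_equal(pan$ratios["A", ], c(b1 = 2, b2 = 2, b3 = 1))
    expect_true(is.na(pan$ratios["B", "b2"]))
    expect_false(anyNA(pan$ratios["B", c("b1", "b3")]))
    # single-member complex: median equals its ratio
    cat1 <- complexCatalog(data.frame(complex = "C1", protein = "A",
                                      subunit_class = "core"))
    pan1 <- bandRatioPanel(x, cat1, "C1", "WT", "MUT", bm)
    expect_equal(unname(pan1$medians), unname(pan1$ratios[1, ]))
})

test_that("all-bands total equals the sum over a partitioning band map", {
    cube <- randomCube(3, 8, c("WT_1", "WT_2"), seed = 29)
    x <- toyExperiment(list(WT_1 = cube[, , 1], WT_2 = cube[, , 2]))
    bm <- bandMap(list(top = 1:3, mid = 4:5, bottom = 6:8))
    for (p in rownames(x)) {
        parts <- vapply(bandLabels(bm), function(b)
            totalAbundance(x, "WT", p, b, bm), numeric(1))
        expect_equal(sum(parts), totalAbundance(x, "WT", p))
    }
})

test_that("swapping groups reciprocates ratios and odd-n medians", {
    cube <- randomCube(5, 4, c("WT_1", "MUT_1"), seed = 31)
    cube[cube < 5] <- 5  # keep everything detected
    x <- toyExperiment(list(WT_1 = cube[, , 1], MUT_1 = cube[, , 2]),
                       group = c("WT", "MUT"), replicate = c(1, 1))
    cat <- complexCatalog(data.frame(complex = "C",
                                     protein = rownames(x),
                                     subunit_class = "core"))
    fwd <- complexRatioTable(x, cat, "C", "WT", "MUT")
    rev <- complexRatioTable(x, cat, "C", "MUT", "WT")
    expect_equal(rev$entries$ratio, 1 / fwd$entries$ratio, tolerance = 1e-12)
    # odd n: median of reciprocals is the reciprocal of the median
    expect_equal(rev$median_ratio, 1 / fwd$median_ratio, tolerance = 1e-12)
})

test_that("display rounding is half away from zero", {
    expect_equal(roundHalfUp(0.985), 0.99)
    expect_equal(roundHalfUp(0.984), 0.98)
    expect_equal(roundHalfUp(-0.985), -0.99)
    expect_equal(roundHalfUp(1.25, 1), 1.3)  # round() would give 1.2
    expect_true(is.na(roundHalfUp(NA_real_)))
})
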