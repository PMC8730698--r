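test_that("consensus profiles average max-scaled member means", {
    S <- 5
    shape <- c(0, 1, 4, 1, 0)
    mk <- function(rows) matrix(unlist(rows), length(rows), S, byrow = TRUE,
                                dimnames = list(names(rows)))
    x <- toyExperiment(list(WT_1 = mk(list(A = shape, B = 3 * shape,
                                           C = rep(0, S)))))
    one <- consensusProfile(x, "WT", "A")
    expect_equal(one$consensus, maxScale(shape))
    # same shape, different amplitude: consensus is that shape, peak 1
    two <- consensusProfile(x, "WT", c("A", "B"))
    expect_equal(two$consensus, maxScale(shape))
    expect_equal(max(two$consensus), 1)
    # undetected member excluded and reported
    three <- consensusProfile(x, "WT", c("A", "C"))
    expect_identical(three$excluded, "C")
    expect_equal(three$consensus, maxScale(shape))
    expect_error(consensusProfile(x, "WT", "C"), "no member detected")
    expect_error(consensusProfile(x, "WT", character()), "empty")
    # brute force for 5 random members
    cube <- randomCube(5, 6, "WT_1", seed = 41)
    xr <- toyExperiment(list(WT_1 = cube[, , 1]))
    cons <- consensusProfile(xr, "WT", rownames(xr))
    brute <- rowMeans(vapply(rownames(xr),
                             function(p) maxScale(cube[p, , 1]),
                             numeric(6)))
    expect_equal(cons$consensus, unname(brute))
})

test_that("profile similarity is Pearson on max-scaled profiles", {
    cons <- maxScale(c(0, 1, 5, 2, 0))
    expect_equal(profileSimilarity(c(0, 1, 5, 2, 0), cons), 1)
    # positive affine transform of the consensus still correlates at 1
    expect_equal(profileSimilarity(3 * c(0, 1, 5, 2, 0) + 1, cons), 1)
    expect_equal(profileSimilarity(c(2, 2, 2, 2, 2), cons), 0)
    expect_error(profileSimilarity(rep(0, 5), cons), "all-zero")
    expect_error(profileSimilarity(c(1, 2), cons), "length")
    set.seed(43)
    for (i in 1:20) {
        a <- runif(8); b <- runif(8)
        expect_equal(profileSimilarity(a, b), cor(maxScale(a), b))
    }
})

test_that("co-migration screen applies the four criteria with recorded reasons", {
    sc <- defaultStudyScenario(cv = 0, dropout = 0, scaleRange = c(1, 1))
    x <- simulateExperiment(sc$truth, sc$design, seed = 2)
    nx <- filterProteotypic(normalized(normalizeTotalIon(x)))
    members <- complexMembers(sc$catalog, "PSII")$protein
    scr <- screenComigrating(nx, members, "WT", "lpa2")
    expect_identical(scr$candidates$protein, c("CAND1", "CAND2"))
    expect_true(all(scr$candidates$similarity_a > 0.99))
    diag <- scr$diagnostics
    expect_false(any(members %in% diag$protein))  # members not candidates
    expect_match(diag$failure[diag$protein == "DECOY_CTP"], "criterion iii")
    expect_match(diag$failure[diag$protein == "DECOY_CONS"], "criterion iv")
    expect_match(diag$failure[diag$protein == "DECOY_SHIFT"], "criterion i")
    expect_error(screenComigrating(nx, character(), "WT", "lpa2"), "empty")
})

test_that("detection criterion (ii) needs two replicates in at least one group", {
    S <- 4
    shape <- c(0, 4, 1, 0)
    mkm <- function(a, b, c) matrix(c(shape, a * shape, b * shape, c * shape),
                                    4, S, byrow = TRUE,
                                    dimnames = list(c("M", "ONCE", "TWICE",
                                                      "FLAT")))
    # ONCE appears in exactly one replicate per group; TWICE in two of one
    wt1 <- mkm(1, 1, 0); wt1["FLAT", ] <- c(1, 1, 1, 1)
    wt2 <- mkm(0, 1, 0); wt2["FLAT", ] <- c(1, 1, 1, 1)
    mut1 <- mkm(1, 1, 0); mut1["FLAT", ] <- c(1, 1, 1, 1)
    mut2 <- mkm(0, 0, 0); mut2["FLAT", ] <- c(1, 1, 1, 1)
    ann <- toyAnnotations(c("M", "ONCE", "TWICE", "FLAT"))
    x <- toyExperiment(list(WT_1 = wt1, WT_2 = wt2, MUT_1 = mut1,
                            MUT_2 = mut2),
                       group = c("WT", "WT", "MUT", "MUT"),
                       replicate = c(1, 2, 1, 2), annotations = ann)
    scr <- screenComigrating(x, "M", "WT", "MUT", minSimilarity = 0.8,
                             minReplicates = 2)
    diag <- scr$diagnostics
    expect_match(diag$failure[diag$protein == "ONCE"], "criterion ii")
    expect_false("ONCE" %in% scr$candidates$protein)
    expect_true("TWICE" %in% scr$candidates$protein)
})

test_that("band-enrichment screen gates on fold with the nd->Inf convention", {
    S <- 5
    mk <- function(rows) matrix(unlist(rows), length(rows), S, byrow = TRUE,
                                dimnames = list(names(rows)))
    rows_wt <- list(E = c(0, 0, 1, 0, 0), I = c(0, 0, 0, 0, 0),
                    U = c(0, 0, 5, 0, 0))
    rows_mut <- list(E = c(0, 0, 10, 0, 0), I = c(0, 0, 3, 0, 0),
                     U = c(0, 0, 5, 0, 0))
    ann <- toyAnnotations(c("E", "I", "U"))
    x <- toyExperiment(list(WT_1 = mk(rows_wt), WT_2 = mk(rows_wt),
                            MUT_1 = mk(rows_mut), MUT_2 = mk(rows_mut)),
                       group = c("WT", "WT", "MUT", "MUT"),
                       replicate = c(1, 2, 1, 2), annotations = ann)
    bm <- bandMap(list(b17 = 3))
    scr <- screenBandEnriched(x, "b17", bm, "WT", "MUT", minFold = 4)
    expect_identical(scr$candidates$protein, c("I", "E"))  # Inf fold first
    expect_equal(scr$candidates$band_fold, c(Inf, 10))
    expect_false("U" %in% scr$candidates$protein)
    expect_match(scr$diagnostics$failure[scr$diagnostics$protein == "U"],
                 "fold gate")
    expect_error(screenBandEnriched(x, "nope", bm, "WT", "MUT"),
                 "unknown band")
    expect_error(screenBandEnriched(x, "b17", bm, "WT", "MUT", minFold = 1),
                 "exceed 1")
})

test_that("planted band-enriched proteins are recovered exactly from background", {
    truth <- bandScreenTruth()
    des <- twoGroupDesign()
    bm <- bandMap(list(RC47 = 17))
    for (seed in 1:3) {
        x <- simulateExperiment(truth, des, seed)
        nx <- normalized(normalizeTotalIon(x))
        scr <- screenBandEnriched(nx, "RC47", bm, "WT", "MUT")
        expect_setequal(scr$candidates$protein, c("ENR1", "ENR2", "ENR3"))
    }
})

test_that("screens are monotone in their thresholds and order-invariant", {
    sc <- defaultStudyScenario(cv = 0.2, dropout = 0)
    x <- simulateExperiment(sc$truth, sc$design, seed = 9)
    nx <- filterProteotypic(normalized(normalizeTotalIon(x)))
    members <- complexMembers(sc$catalog, "PSII")$protein
    strict <- screenComigrating(nx, members, "WT", "lpa2",
                                minSimilarity = 0.9)$candidates$protein
    loose <- screenComigrating(nx, members, "WT", "lpa2",
                               minSimilarity = 0.5)$candidates$protein
    expect_true(all(strict %in% loose))
    bstrict <- screenBandEnriched(nx, "RC47", sc$bands, "WT", "lpa2",
                                  minFold = 8)$candidates$protein
    bloose <- screenBandEnriched(nx, "RC47", sc$bands, "WT", "lpa2",
                                 minFold = 2)$candidates$protein
    expect_true(all(bstrict %in% bloose))
    # permuting protein rows leaves the result unchanged
    perm <- nx[rev(rownames(nx)), ]
    scr1 <- screenComigrating(nx, members, "WT", "lpa2")
    scr2 <- screenComigrating(perm, members, "WT", "lpa2")
    expect_identical(scr1$candidates$protein, scr2$candidates$protein)
    expect_identical(scr1$diagnostics$protein, scr2$diagnostics$protein)
})
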