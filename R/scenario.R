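#' Ready-made synthetic scenario emulating the lpa2 complexome study
#'
#' A 36-slice, two-group (WT vs lpa2) x 3-replicate scenario containing:
#' a 9-subunit PSII-like complex whose four assembly states (bands 4, 10,
#' 15, 17 = supercomplexes, dimers, monomers, RC47) are occupied in the
#' mutant at 0.07, 0.27, 0.60 and 6.05 times the wild-type level; an
#' unchanged cytochrome-b6f-like complex (all occupancies 1); an ATP
#' synthase-like complex increased 1.29-fold in the mutant; 50 background
#' singleton proteins; planted co-migration screen candidates sharing the
#' PSII ladder (CAND1, CAND2) with correct annotation flags; decoys (a
#' peak-shifted ladder and flag-failing ladder proteins); and three
#' band-17 enriched proteins (ENR1-3, 10-fold).  A free-protein ballast
#' pool balances the expected per-group totals exactly, emulating equal
#' protein loading per lane, so that total-ion normalization is unbiased.
#' Ladder state widths are 0.25 slices so that neighbouring bands (15 and
#' 17 are two slices apart) do not bleed into each other and noiseless
#' band ratios recover the occupancy multipliers to numerical precision.
#'
#' @param cv replicate noise CV (study-level default 0.2).
#' @param dropout detection dropout probability (default 0.05).
#' @param scaleRange per-sample lane scale range (default c(0.5, 2)),
#'   emulating the between-lane total-intensity differences that motivate
#'   normalization.
#' @return list with elements \code{truth} ([SyntheticTruth-class]),
#'   \code{design} (3 WT + 3 lpa2 samples), \code{bands}
#'   ([studyBandMap()]), \code{catalog}, \code{psii_multipliers}, and
#'   \code{planted} (ids of candidates, decoys and enriched proteins).
#' @export
defaultStudyScenario <- function(cv = 0.2, dropout = 0.05,
                                 scaleRange = c(0.5, 2)) {
    S <- 36L
    w <- 0.25
    mult <- c(SC = 0.07, dimer = 0.27, monomer = 0.60, RC47 = 6.05)
    wtOcc <- c(SC = 1.0, dimer = 0.45, monomer = 0.25, RC47 = 0.05)
    centers <- c(SC = 4, dimer = 10, monomer = 15, RC47 = 17)
    ladder <- function(cx, shift = 0, occScale = 1) do.call(rbind, lapply(
        names(mult), function(st) assemblyState(
            cx, st, centers[[st]] + shift,
            c(WT = wtOcc[[st]],
              lpa2 = wtOcc[[st]] * mult[[st]]) * occScale, w)))
    states <- rbind(
        ladder("PSII"),
        assemblyState("cyt_b6f", "dimer", 12, c(WT = 1, lpa2 = 1), w),
        assemblyState("atp_synthase", "holo", 8, c(WT = 1, lpa2 = 1.29), w),
        ladder("cand_ladder"),
        ladder("decoy_shift", shift = 6),
        assemblyState("enriched17", "RC47", 17, c(WT = 0.03, lpa2 = 0.3), w))
    psii <- data.frame(
        protein = c("PsbA", "PsbB", "PsbC", "PsbD", "PsbE", "PsbF",
                    "PsbJ", "PsbL", "PBA1"),
        complex = "PSII",
        amplitude = c(5.0e8, 4.5e8, 4.8e8, 4.6e8, 1.5e8, 1.1e8,
                      6.0e7, 5.0e7, 2.5e7),
        proteotypic = TRUE,
        has_ctp = c(rep(FALSE, 8L), TRUE),  # plastome-encoded cores lack a cTP
        conserved = TRUE, subunit_class = "core", in_catalog = TRUE)
    b6f <- data.frame(
        protein = c("PetA", "PetB", "PETC", "PetD"), complex = "cyt_b6f",
        amplitude = c(3.0e8, 2.6e8, 2.2e8, 1.8e8), proteotypic = TRUE,
        has_ctp = c(FALSE, FALSE, TRUE, FALSE), conserved = TRUE,
        subunit_class = "core", in_catalog = TRUE)
    atp <- data.frame(
        protein = c("AtpA", "AtpB", "ATPC", "ATPD", "AtpE"),
        complex = "atp_synthase",
        amplitude = c(6.0e8, 6.2e8, 1.5e8, 1.2e8, 1.0e8),
        proteotypic = TRUE, has_ctp = c(FALSE, FALSE, TRUE, TRUE, FALSE),
        conserved = TRUE, subunit_class = "core", in_catalog = TRUE)
    nb <- 50L
    i <- seq_len(nb)
    bgCenter <- 2 + (i * 7) %% 33          # spread over slices 2..34
    bgStates <- do.call(rbind, lapply(i, function(j) assemblyState(
        sprintf("bg%02d", j), "pool", bgCenter[j], c(WT = 1, lpa2 = 1),
        width = 0.7)))
    bg <- data.frame(
        protein = sprintf("BG%02d", i), complex = sprintf("bg%02d", i),
        amplitude = 10^(6.5 + 1.5 * ((i * 0.6180339887) %% 1)),
        proteotypic = i %% 17 != 0, has_ctp = i %% 2 == 0,
        conserved = i %% 3 != 0, subunit_class = NA_character_,
        in_catalog = FALSE)
    states <- rbind(states, bgStates)
    planted <- data.frame(
        protein = c("CAND1", "CAND2", "DECOY_SHIFT", "DECOY_CTP",
                    "DECOY_CONS", "ENR1", "ENR2", "ENR3"),
        complex = c("cand_ladder", "cand_ladder", "decoy_shift",
                    "cand_ladder", "cand_ladder", "enriched17",
                    "enriched17", "enriched17"),
        amplitude = c(4.0e7, 2.5e7, 3.0e7, 3.0e7, 3.0e7,
                      2.0e7, 1.5e7, 1.2e7),
        proteotypic = TRUE,
        has_ctp = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
        conserved = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
        subunit_class = NA_character_, in_catalog = FALSE)
    proteins <- rbind(psii, b6f, atp, bg, planted)
    proteins$description <- ""
    # ballast pool balancing the expected per-group totals (equal protein
    # load per lane); occupancy solved so both group totals hit the same
    # target
    gsum <- function(center, width)
        sum(exp(-(seq_len(S) - center)^2 / (2 * width^2)))
    groupTotal <- function(g) {
        tot <- 0
        for (r in seq_len(nrow(proteins))) {
            st <- states[states$complex == proteins$complex[r] &
                         states$group == g, , drop = FALSE]
            tot <- tot + proteins$amplitude[r] *
                sum(st$occupancy * mapply(gsum, st$center, st$width))
        }
        tot
    }
    totals <- c(WT = groupTotal("WT"), lpa2 = groupTotal("lpa2"))
    target <- max(totals) * 1.05
    ballastAmp <- 5e8
    ballastG <- gsum(30, 0.7)
    states <- rbind(states, assemblyState(
        "ballast", "pool", 30,
        (target - totals) / (ballastAmp * ballastG), width = 0.7))
    proteins <- rbind(proteins, data.frame(
        protein = "BALLAST", complex = "ballast", amplitude = ballastAmp,
        proteotypic = TRUE, has_ctp = FALSE, conserved = FALSE,
        subunit_class = NA_character_, in_catalog = FALSE,
        description = ""))
    truth <- syntheticTruth(S, proteins, states, cv = cv,
                            dropout = dropout, scaleRange = scaleRange)
    design <- sampleDesign(
        c("WT_1", "WT_2", "WT_3", "lpa2_1", "lpa2_2", "lpa2_3"),
        rep(c("WT", "lpa2"), each = 3L), rep(1:3, 2L))
    list(truth = truth, design = design, bands = studyBandMap(),
         catalog = truthCatalog(truth), psii_multipliers = mult,
         planted = list(candidates = c("CAND1", "CAND2"),
                        decoys = c("DECOY_SHIFT", "DECOY_CTP", "DECOY_CONS"),
                        enriched = c("ENR1", "ENR2", "ENR3")))
}
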