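# In-code fixtures shared across test files.

# Build a small experiment from a [protein, slice, sample] cube given as a
# list of per-sample matrices (proteins x slices).
toyExperiment <- function(perSample, group = NULL, replicate = NULL,
                          annotations = NULL) {
    samples <- names(perSample)
    nP <- nrow(perSample[[1L]])
    S <- ncol(perSample[[1L]])
    cube <- array(0, dim = c(nP, S, length(samples)),
                  dimnames = list(rownames(perSample[[1L]]), NULL, samples))
    for (s in samples) cube[, , s] <- perSample[[s]]
    if (is.null(group)) {
        d <- complexomics:::.inferDesign(samples)
    } else {
        d <- sampleDesign(samples, group, replicate)
    }
    ComplexomeExperiment(cube, d, annotations = annotations)
}

# Deterministic random cube with the given dims, nonnegative.
randomCube <- function(nP, S, samples, seed = 1) {
    set.seed(seed)
    cube <- array(round(runif(nP * S * length(samples), 0, 100), 3),
                  dim = c(nP, S, length(samples)),
                  dimnames = list(sprintf("P%02d", seq_len(nP)), NULL,
                                  samples))
    cube
}

toyAnnotations <- function(proteins, proteotypic = TRUE, has_ctp = TRUE,
                           conserved = TRUE) {
    n <- length(proteins)
    data.frame(protein = proteins, description = "",
               proteotypic = rep_len(proteotypic, n),
               has_ctp = rep_len(has_ctp, n),
               conserved = rep_len(conserved, n),
               complex = NA_character_, subunit_class = NA_character_)
}

# A dedicated band-enrichment scenario: nBackground unchanged singletons
# plus three proteins planted 10-fold enriched in the RC47 band of the
# mutant, all flags passing.
bandScreenTruth <- function(nBackground = 50L, cv = 0.1, dropout = 0) {
    i <- seq_len(nBackground)
    states <- do.call(rbind, c(
        lapply(i, function(j) assemblyState(
            sprintf("bg%02d", j), "pool", 2 + (j * 5) %% 30,
            c(WT = 1, MUT = 1), width = 0.7)),
        list(assemblyState("enr", "RC47", 17, c(WT = 0.05, MUT = 0.5),
                           width = 0.25))))
    proteins <- rbind(
        data.frame(protein = sprintf("BG%02d", i),
                   complex = sprintf("bg%02d", i),
                   amplitude = 1e6 + 1e5 * i, proteotypic = TRUE,
                   has_ctp = i %% 2 == 0, conserved = TRUE,
                   subunit_class = NA, in_catalog = FALSE),
        data.frame(protein = c("ENR1", "ENR2", "ENR3"), complex = "enr",
                   amplitude = c(2e6, 3e6, 4e6), proteotypic = TRUE,
                   has_ctp = TRUE, conserved = TRUE, subunit_class = NA,
                   in_catalog = FALSE))
    syntheticTruth(36L, proteins, states, cv = cv, dropout = dropout)
}

twoGroupDesign <- function(groups = c("WT", "MUT"), n = 3L)
    sampleDesign(sprintf("%s_%d", rep(groups, each = n), rep(seq_len(n), 2)),
                 rep(groups, each = n), rep(seq_len(n), 2))
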