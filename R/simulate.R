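#' Build an assembly-state table row
#'
#' One assembly state of a complex: a Gaussian band in slice space with a
#' per-group occupancy multiplier.  Widths are Gaussian sigma in slice
#' units; the default 0.7 approximates a sub-slice-width band.
#'
#' @param complex component identifier the state belongs to.
#' @param state state name (e.g. "SC", "dimer").
#' @param center peak slice position (real, in [1, S]).
#' @param occupancy named numeric, group label -> nonnegative multiplier.
#' @param width Gaussian sigma in slice units (> 0).
#' @return data.frame in the long states format of
#'   [syntheticTruth()].
#' @export
assemblyState <- function(complex, state, center, occupancy, width = 0.7) {
    if (is.null(names(occupancy)))
        stop("'occupancy' must be named by group")
    data.frame(complex = complex, state = state, center = center,
               width = width, group = names(occupancy),
               occupancy = as.numeric(occupancy), row.names = NULL)
}

#' Construct the ground truth of a synthetic complexome experiment
#'
#' @param nSlices number of gel slices S.
#' @param proteins data.frame: protein, complex, amplitude, and the
#'   annotation flags proteotypic, has_ctp, conserved; optional
#'   description, subunit_class, in_catalog.
#' @param states long data.frame of assembly states (rows from
#'   [assemblyState()]).
#' @param cv replicate coefficient of variation of the multiplicative
#'   log-normal noise (>= 0).
#' @param dropout detection dropout probability in [0, 1].
#' @param scaleRange range of per-sample global scale factors, drawn
#'   uniformly at simulation time (c(1, 1) disables lane-scale offsets).
#' @return a [SyntheticTruth-class].
#' @export
syntheticTruth <- function(nSlices, proteins, states, cv = 0,
                           dropout = 0, scaleRange = c(1, 1)) {
    proteins <- as.data.frame(proteins)
    if (is.null(proteins$description)) proteins$description <- ""
    if (is.null(proteins$subunit_class))
        proteins$subunit_class <- NA_character_
    if (is.null(proteins$in_catalog)) proteins$in_catalog <- FALSE
    obj <- methods::new("SyntheticTruth", nSlices = as.integer(nSlices),
                        proteins = proteins, states = as.data.frame(states),
                        cv = cv, dropout = dropout,
                        scaleRange = as.numeric(scaleRange))
    methods::validObject(obj)
    obj
}

#' @describeIn syntheticTruth group labels with defined occupancies.
#' @param truth a SyntheticTruth.
#' @export
truthGroups <- function(truth) unique(truth@states$group)

#' Noise-free expected migration profile
#'
#' Closed-form Gaussian-mixture expectation of one protein in one group:
#' \code{amplitude * sum_states occupancy(group) *
#' exp(-(k - center)^2 / (2 width^2))} over slices k = 1..S.
#'
#' @param truth a [SyntheticTruth-class].
#' @param protein protein identifier.
#' @param group group label.
#' @return numeric vector of length S.
#' @export
expectedProfile <- function(truth, protein, group) {
    i <- match(protein, truth@proteins$protein)
    if (is.na(i)) stop(sprintf("unknown protein '%s'", protein))
    st <- truth@states
    st <- st[st$complex == truth@proteins$complex[i] & st$group == group, ,
             drop = FALSE]
    if (!nrow(st)) stop(sprintf("unknown group '%s'", group))
    k <- seq_len(truth@nSlices)
    v <- rep(0, truth@nSlices)
    for (j in seq_len(nrow(st)))
        v <- v + st$occupancy[j] *
            exp(-(k - st$center[j])^2 / (2 * st$width[j]^2))
    truth@proteins$amplitude[i] * v
}

#' @describeIn syntheticTruth annotation table implied by the truth.
#' @export
truthAnnotations <- function(truth) {
    p <- truth@proteins
    .checkAnnotations(data.frame(
        protein = p$protein, description = p$description,
        proteotypic = p$proteotypic, has_ctp = p$has_ctp,
        conserved = p$conserved,
        complex = ifelse(p$in_catalog, p$complex, NA_character_),
        subunit_class = ifelse(p$in_catalog, p$subunit_class,
                               NA_character_)))
}

#' @describeIn syntheticTruth complex catalog of the cataloged components.
#' @export
truthCatalog <- function(truth) {
    p <- truth@proteins[truth@proteins$in_catalog, , drop = FALSE]
    if (!nrow(p)) stop("truth has no cataloged complexes")
    complexCatalog(data.frame(complex = p$complex, protein = p$protein,
                              subunit_class = p$subunit_class))
}

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
            else if (exists(".Random.seed", envir = .GlobalEnv,
                            inherits = FALSE))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    code
}

#' Simulate a complexome profiling experiment
#'
#' Draws per-sample global scale factors uniformly from the truth's
#' \code{scaleRange}, multiplies each expected intensity by the sample
#' scale and by unit-mean multiplicative log-normal noise with the
#' truth's CV (\code{sdlog = sqrt(log(1 + cv^2))}), then zeroes each
#' nonzero cell independently with the dropout probability.  All
#' randomness flows from \code{seed}; the caller's RNG state is left
#' untouched and the same seed gives bit-identical output.
#'
#' @param truth a [SyntheticTruth-class].
#' @param design a [sampleDesign()] whose groups are a subset of the
#'   truth's groups.
#' @param seed integer seed.
#' @return a [ComplexomeExperiment-class] with truth-consistent
#'   annotations attached; the drawn per-sample scale factors and the
#'   seed are recorded in \code{metadata(x)$simulation}.
#' @export
simulateExperiment <- function(truth, design, seed) {
    design <- sampleDesign(design$sample, design$group, design$replicate)
    bad <- setdiff(design$group, truthGroups(truth))
    if (length(bad))
        stop(sprintf("design group(s) not in truth: %s",
                     paste(bad, collapse = ", ")))
    S <- truth@nSlices
    prot <- truth@proteins$protein
    expected <- lapply(unique(design$group), function(g)
        t(vapply(prot, function(p) expectedProfile(truth, p, g),
                 numeric(S))))
    names(expected) <- unique(design$group)
    .withSeed(seed, {
        # raw uniforms + affine transform so a degenerate scale range
        # consumes the same stream as a proper one (paired-seed runs stay
        # comparable)
        scales <- truth@scaleRange[1L] + diff(truth@scaleRange) *
            stats::runif(nrow(design))
        names(scales) <- design$sample
        cube <- array(0, dim = c(length(prot), S, nrow(design)),
                      dimnames = list(prot, NULL, design$sample))
        sdlog <- sqrt(log(1 + truth@cv^2))
        for (si in seq_len(nrow(design))) {
            e <- expected[[design$group[si]]] * scales[si]
            if (truth@cv > 0)
                e <- e * matrix(stats::rlnorm(length(e),
                                              meanlog = -sdlog^2 / 2,
                                              sdlog = sdlog),
                                nrow = nrow(e))
            if (truth@dropout > 0) {
                drop <- matrix(stats::runif(length(e)) < truth@dropout,
                               nrow = nrow(e))
                e[drop & e > 0] <- 0
            }
            cube[, , si] <- e
        }
        x <- ComplexomeExperiment(cube, design,
                                  annotations = truthAnnotations(truth))
        S4Vectors::metadata(x)$simulation <-
            list(seed = seed, scales = scales, cv = truth@cv,
                 dropout = truth@dropout)
        x
    })
}
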