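#' ComplexomeExperiment: slice-resolved protein intensities
#'
#' A \linkS4class{SummarizedExperiment} holding one BN-PAGE complexome
#' profiling experiment.  Rows are proteins; columns are (sample, slice)
#' pairs, i.e. one gel-slice digest of one lane.  The single assay
#' \code{"intensity"} holds nonnegative ion intensities; a missing value is
#' encoded as exact 0 (the convention of protein-group intensity exports),
#' and "detected" means nonzero downstream.  \code{colData} carries the
#' sample design: \code{sample}, \code{slice} (1-based, slice 1 = top of the
#' gel), \code{group} and \code{replicate}.
#'
#' @slot .. no additional slots; the class adds validity constraints and
#'   complexome-specific accessors on top of SummarizedExperiment.
#'
#' @seealso [ComplexomeExperiment()] for construction from an intensity
#'   cube, [nSlices()], [intensityCube()], [designTable()].
#' @export
setClass("ComplexomeExperiment", contains = "SummarizedExperiment")

setValidity("ComplexomeExperiment", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample", "slice", "group", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(sprintf("colData lacks column(s): %s",
                       paste(miss, collapse = ", ")))
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' is missing")
    a <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(a) || any(!is.finite(a)))
        msg <- c(msg, "intensities must be finite and non-missing")
    else if (any(a < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein identifiers (rownames) must be unique")
    sm <- as.character(cd$sample)
    sl <- as.integer(cd$slice)
    S <- suppressWarnings(max(sl))
    for (s in unique(sm)) {
        k <- sort(sl[sm == s])
        if (!identical(k, seq_len(S)))
            msg <- c(msg, sprintf(
                "sample '%s' does not cover slices 1..%d exactly once", s, S))
        if (length(unique(cd$group[sm == s])) != 1L ||
            length(unique(cd$replicate[sm == s])) != 1L)
            msg <- c(msg, sprintf(
                "sample '%s' maps to more than one (group, replicate)", s))
    }
    des <- unique(data.frame(sample = sm, group = as.character(cd$group),
                             replicate = as.integer(cd$replicate)))
    if (anyDuplicated(des[, c("group", "replicate")]))
        msg <- c(msg, "(group, replicate) pairs must be unique")
    if (length(msg)) msg else TRUE
})

#' Named bands on the BN gel
#'
#' Maps a band label (for example \code{"SC"}, \code{"dimer"},
#' \code{"monomer"}, \code{"RC47"}) to one or more contiguous slice indices.
#'
#' @slot bands named list of integer vectors of slice indices.
#' @seealso [bandMap()], [studyBandMap()], [readBandMap()]
#' @export
setClass("BandMap", representation(bands = "list"))

setValidity("BandMap", function(object) {
    b <- object@bands
    if (length(b) == 0L) return("band map is empty")
    if (is.null(names(b)) || any(names(b) == "") || anyDuplicated(names(b)))
        return("band labels must be unique and non-empty")
    for (nm in names(b)) {
        k <- b[[nm]]
        if (!is.numeric(k) || length(k) == 0L || any(k != as.integer(k)) ||
            any(k < 1))
            return(sprintf("band '%s' must name positive integer slices", nm))
        k <- sort(as.integer(k))
        if (length(k) > 1L && any(diff(k) != 1L))
            return(sprintf("band '%s' slices must be contiguous", nm))
    }
    TRUE
})

#' Catalog of protein complexes and their subunits
#'
#' @slot members data.frame with columns \code{complex}, \code{protein},
#'   \code{subunit_class} (one of core, antenna, oec, auxiliary, other),
#'   one row per subunit, member order preserved.
#' @seealso [complexCatalog()], [readComplexCatalog()]
#' @export
setClass("ComplexCatalog", representation(members = "data.frame"))

setValidity("ComplexCatalog", function(object) {
    m <- object@members
    need <- c("complex", "protein", "subunit_class")
    if (!all(need %in% colnames(m)))
        return(sprintf("members needs columns: %s", paste(need, collapse = ", ")))
    if (nrow(m) == 0L) return("catalog has no members")
    if (anyDuplicated(m[, c("complex", "protein")]))
        return("member protein ids must be unique within a complex")
    ok <- c("core", "antenna", "oec", "auxiliary", "other")
    bad <- setdiff(unique(as.character(m$subunit_class)), ok)
    if (length(bad))
        return(sprintf("unknown subunit_class: %s", paste(bad, collapse = ", ")))
    TRUE
})

#' Result of total-ion-intensity normalization
#'
#' @slot factors named per-sample correction factors, total/grand-mean.
#' @slot preTotals named per-sample total ion intensities before scaling.
#' @slot grandMean arithmetic mean of the pre-normalization totals.
#' @slot normalized the normalized [ComplexomeExperiment].
#' @seealso [normalizeTotalIon()]
#' @export
setClass("TICNormalization",
         representation(factors = "numeric", preTotals = "numeric",
                        grandMean = "numeric",
                        normalized = "ComplexomeExperiment"))

#' Ground truth of a synthetic complexome experiment
#'
#' Encodes per-protein Gaussian-mixture migration profiles: each protein
#' belongs to one component (a multi-state complex or its own singleton
#' pool); each assembly state is a Gaussian in slice space with a
#' per-group occupancy multiplier.  The expected intensity of protein p in
#' group g at slice k is
#' \code{amplitude(p) * sum_states occupancy(g) * exp(-(k-center)^2/(2*width^2))}.
#'
#' @slot nSlices integer number of gel slices S.
#' @slot proteins data.frame: protein, complex (component id), amplitude,
#'   description, proteotypic, has_ctp, conserved, subunit_class,
#'   in_catalog (logical: list this component in the complex catalog).
#' @slot states data.frame (long): complex, state, center, width, group,
#'   occupancy.
#' @slot cv replicate coefficient of variation of the multiplicative
#'   log-normal noise.
#' @slot dropout probability that a nonzero cell is zeroed (detection
#'   dropout).
#' @slot scaleRange length-2 range from which per-sample global scale
#'   factors are drawn uniformly at simulation time.
#' @seealso [syntheticTruth()], [simulateExperiment()],
#'   [defaultStudyScenario()]
#' @export
setClass("SyntheticTruth",
         representation(nSlices = "integer", proteins = "data.frame",
                        states = "data.frame", cv = "numeric",
                        dropout = "numeric", scaleRange = "numeric"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    p <- object@proteins; st <- object@states
    if (anyDuplicated(p$protein)) msg <- c(msg, "duplicate protein ids")
    if (any(!p$complex %in% st$complex))
        msg <- c(msg, "every protein must reference a component with states")
    if (any(st$width <= 0)) msg <- c(msg, "state widths must be > 0")
    if (any(st$occupancy < 0)) msg <- c(msg, "occupancies must be >= 0")
    if (any(st$center < 1 | st$center > object@nSlices))
        msg <- c(msg, "state centers must lie in [1, nSlices]")
    if (object@cv < 0 || object@dropout < 0 || object@dropout > 1)
        msg <- c(msg, "cv must be >= 0 and dropout in [0, 1]")
    if (length(object@scaleRange) != 2L || any(object@scaleRange <= 0) ||
        diff(object@scaleRange) < 0)
        msg <- c(msg, "scaleRange must be an increasing positive pair")
    if (length(msg)) msg else TRUE
})
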