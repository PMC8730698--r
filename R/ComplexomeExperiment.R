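#' Construct a ComplexomeExperiment from an intensity cube
#'
#' @param intensity numeric array \code{[protein, slice, sample]} with
#'   dimnames on the protein and sample dimensions, or a matrix of
#'   proteins x (sample,slice) columns matching \code{design}.
#'   Nonnegative; missing values must already be encoded as 0.
#' @param design a sample design as returned by [sampleDesign()]: one row
#'   per sample with columns \code{sample}, \code{group}, \code{replicate}.
#' @param annotations optional protein annotation data.frame (see
#'   [readAnnotations()]); matched by protein id and stored in
#'   \code{rowData}.
#' @return a [ComplexomeExperiment-class] object.
#' @examples
#' cube <- array(runif(2 * 3 * 2), dim = c(2, 3, 2),
#'               dimnames = list(c("P1", "P2"), NULL, c("WT_1", "MUT_1")))
#' des <- sampleDesign(c("WT_1", "MUT_1"), c("WT", "MUT"), c(1, 1))
#' ce <- ComplexomeExperiment(cube, des)
#' nSlices(ce)
#' @export
ComplexomeExperiment <- function(intensity, design, annotations = NULL) {
    design <- sampleDesign(design$sample, design$group, design$replicate)
    if (length(dim(intensity)) != 3L)
        stop("'intensity' must be a 3-d array [protein, slice, sample]")
    S <- dim(intensity)[2L]
    samples <- dimnames(intensity)[[3L]]
    if (is.null(samples)) samples <- design$sample
    if (!setequal(samples, design$sample))
        stop("samples of 'intensity' and 'design' disagree")
    intensity <- intensity[, , design$sample, drop = FALSE]
    mat <- matrix(aperm(intensity, c(1L, 2L, 3L)),
                  nrow = dim(intensity)[1L],
                  dimnames = list(dimnames(intensity)[[1L]], NULL))
    cd <- S4Vectors::DataFrame(
        sample = rep(design$sample, each = S),
        slice = rep(seq_len(S), times = nrow(design)),
        group = rep(design$group, each = S),
        replicate = rep(design$replicate, each = S))
    colnames(mat) <- sprintf("%s|slice%d", cd$sample, cd$slice)
    rownames(cd) <- colnames(mat)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = mat), colData = cd)
    obj <- methods::new("ComplexomeExperiment", se)
    if (!is.null(annotations)) annotations(obj) <- annotations
    methods::validObject(obj)
    obj
}

#' Validated sample design
#'
#' @param sample character sample identifiers.
#' @param group group label per sample (e.g. "WT", "lpa2").
#' @param replicate 1-based replicate index per sample.
#' @return data.frame with columns sample, group, replicate.
#' @export
sampleDesign <- function(sample, group, replicate) {
    d <- data.frame(sample = as.character(sample),
                    group = as.character(group),
                    replicate = as.integer(replicate),
                    stringsAsFactors = FALSE)
    if (anyNA(d)) stop("sample design must not contain missing values")
    if (anyDuplicated(d$sample)) stop("duplicate sample identifiers")
    if (anyDuplicated(d[, c("group", "replicate")]))
        stop("(group, replicate) pairs must be unique")
    d
}

#' @describeIn ComplexomeExperiment number of gel slices S.
#' @param x a ComplexomeExperiment.
#' @export
nSlices <- function(x) max(SummarizedExperiment::colData(x)$slice)

#' @describeIn ComplexomeExperiment sample identifiers, in design order.
#' @export
sampleIds <- function(x) unique(as.character(
    SummarizedExperiment::colData(x)$sample))

#' @describeIn ComplexomeExperiment distinct group labels.
#' @export
groupLabels <- function(x) unique(as.character(
    SummarizedExperiment::colData(x)$group))

#' @describeIn ComplexomeExperiment one-row-per-sample design table.
#' @export
designTable <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    d <- unique(data.frame(sample = as.character(cd$sample),
                           group = as.character(cd$group),
                           replicate = as.integer(cd$replicate)))
    rownames(d) <- NULL
    d
}

#' @describeIn ComplexomeExperiment samples belonging to one group.
#' @param group group label.
#' @export
samplesOf <- function(x, group) {
    d <- designTable(x)
    out <- d$sample[d$group == group]
    if (!length(out)) stop(sprintf("unknown group '%s'", group))
    out
}

#' @describeIn ComplexomeExperiment the intensities as a 3-d array
#'   \code{[protein, slice, sample]}.
#' @export
intensityCube <- function(x) {
    S <- nSlices(x)
    sm <- sampleIds(x)
    a <- array(SummarizedExperiment::assay(x, "intensity"),
               dim = c(nrow(x), S, length(sm)),
               dimnames = list(rownames(x), NULL, sm))
    a
}

#' @describeIn ComplexomeExperiment one protein's migration profile in one
#'   sample (numeric vector of length S).
#' @param protein protein identifier.
#' @param sample sample identifier.
#' @export
profileOf <- function(x, protein, sample) {
    if (!protein %in% rownames(x))
        stop(sprintf("unknown protein '%s'", protein))
    cd <- SummarizedExperiment::colData(x)
    j <- which(cd$sample == sample)
    if (!length(j)) stop(sprintf("unknown sample '%s'", sample))
    v <- SummarizedExperiment::assay(x, "intensity")[protein, j]
    as.numeric(v[order(cd$slice[j])])
}

#' @describeIn ComplexomeExperiment protein annotations stored in rowData
#'   (NULL when never attached).
#' @export
annotations <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"proteotypic" %in% colnames(rd)) return(NULL)
    out <- as.data.frame(rd)
    out$protein <- rownames(x)
    rownames(out) <- NULL
    out[, c("protein", setdiff(colnames(out), "protein"))]
}

#' @describeIn ComplexomeExperiment attach protein annotations (a
#'   data.frame with a \code{protein} column) to rowData, matched by id.
#' @param value annotation data.frame.
#' @export
`annotations<-` <- function(x, value) {
    value <- .checkAnnotations(value)
    miss <- setdiff(rownames(x), value$protein)
    if (length(miss))
        stop(sprintf("unannotated protein(s): %s",
                     paste(miss, collapse = ", ")))
    value <- value[match(rownames(x), value$protein), ]
    rd <- S4Vectors::DataFrame(value[, setdiff(colnames(value), "protein"),
                                     drop = FALSE])
    rownames(rd) <- rownames(x)
    SummarizedExperiment::rowData(x) <- rd
    x
}

.checkAnnotations <- function(ann) {
    need <- c("protein", "proteotypic", "has_ctp", "conserved")
    miss <- setdiff(need, colnames(ann))
    if (length(miss))
        stop(sprintf("annotation table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(ann$protein)) stop("duplicate protein id in annotations")
    for (cc in c("proteotypic", "has_ctp", "conserved")) {
        if (!is.logical(ann[[cc]]) || anyNA(ann[[cc]]))
            stop(sprintf("annotation column '%s' must be TRUE/FALSE", cc))
    }
    if (is.null(ann$description)) ann$description <- ""
    if (is.null(ann$complex)) ann$complex <- NA_character_
    if (is.null(ann$subunit_class)) ann$subunit_class <- NA_character_
    ann
}

setMethod("show", "ComplexomeExperiment", function(object) {
    d <- designTable(object)
    cat(sprintf("ComplexomeExperiment: %d proteins x %d slices x %d samples\n",
                nrow(object), nSlices(object), nrow(d)))
    for (g in unique(d$group))
        cat(sprintf("  group %-8s %d replicate(s)\n", g, sum(d$group == g)))
    if (!is.null(annotations(object)))
        cat("  protein annotations attached\n")
    invisible(NULL)
})

#' Construct a BandMap
#'
#' @param bands named list mapping band label to slice index(es); a band
#'   spanning several slices must be contiguous.
#' @return a [BandMap-class].
#' @examples
#' bandMap(list(SC = 4, dimer = 10, monomer = 15, RC47 = 17))
#' @export
bandMap <- function(bands) {
    obj <- methods::new("BandMap", bands = lapply(bands, as.integer))
    methods::validObject(obj)
    obj
}

#' @describeIn bandMap band labels.
#' @param x a BandMap.
#' @export
bandLabels <- function(x) names(x@bands)

#' @describeIn bandMap slice indices of one band.
#' @param band band label.
#' @export
bandSlices <- function(x, band) {
    if (!band %in% names(x@bands)) stop(sprintf("unknown band '%s'", band))
    x@bands[[band]]
}

#' The band map of the study design: slice 4 = PSII supercomplexes,
#' 10 = dimers, 15 = monomers, 17 = RC47.
#' @return a [BandMap-class].
#' @export
studyBandMap <- function()
    bandMap(list(SC = 4, dimer = 10, monomer = 15, RC47 = 17))

setMethod("show", "BandMap", function(object) {
    cat("BandMap:\n")
    for (nm in names(object@bands))
        cat(sprintf("  %-10s slice(s) %s\n", nm,
                    paste(object@bands[[nm]], collapse = ",")))
    invisible(NULL)
})

#' Construct a ComplexCatalog
#'
#' @param members data.frame with columns complex, protein, subunit_class
#'   (core, antenna, oec, auxiliary or other), one row per subunit.
#' @return a [ComplexCatalog-class].
#' @export
complexCatalog <- function(members) {
    members <- as.data.frame(members)
    members$complex <- as.character(members$complex)
    members$protein <- as.character(members$protein)
    members$subunit_class <- as.character(members$subunit_class)
    obj <- methods::new("ComplexCatalog", members = members)
    methods::validObject(obj)
    obj
}

#' @describeIn complexCatalog complex names.
#' @param x a ComplexCatalog.
#' @export
complexNames <- function(x) unique(x@members$complex)

#' @describeIn complexCatalog member table of one complex, in catalog order.
#' @param complex complex name.
#' @export
complexMembers <- function(x, complex) {
    m <- x@members[x@members$complex == complex, , drop = FALSE]
    if (!nrow(m)) stop(sprintf("unknown complex '%s'", complex))
    rownames(m) <- NULL
    m
}

setMethod("show", "ComplexCatalog", function(object) {
    tab <- table(object@members$complex)
    cat(sprintf("ComplexCatalog: %d complexes, %d members\n",
                length(tab), nrow(object@members)))
    for (nm in unique(object@members$complex))
        cat(sprintf("  %-18s %d subunits\n", nm, tab[[nm]]))
    invisible(NULL)
})

setMethod("show", "TICNormalization", function(object) {
    cat(sprintf("TICNormalization over %d samples; grand mean %.4g\n",
                length(object@factors), object@grandMean))
    print(round(object@factors, 4))
    invisible(NULL)
})

#' @describeIn normalizeTotalIon per-sample correction factors.
#' @param x a TICNormalization.
#' @export
normFactors <- function(x) x@factors

#' @describeIn normalizeTotalIon the normalized experiment.
#' @export
normalized <- function(x) x@normalized
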