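#' Per-sample total ion intensities
#'
#' Sum of all protein and gel-slice intensities of each sample (lane).
#' @param x a [ComplexomeExperiment-class].
#' @return named numeric, one total per sample in design order.
#' @export
sampleTotals <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x, "intensity")
    tot <- vapply(sampleIds(x),
                  function(s) sum(a[, cd$sample == s, drop = FALSE]),
                  numeric(1L))
    tot
}

#' Total-ion-intensity normalization
#'
#' Equalizes the per-sample (per-lane) total ion intensity sums: each
#' sample's correction factor is its total divided by the arithmetic mean
#' of all totals, and every intensity is divided by its sample's factor.
#' After normalization every sample total equals the pre-normalization
#' grand mean.  Applied to the matrix as loaded, before any proteotypic
#' filtering.
#'
#' @param x a [ComplexomeExperiment-class].
#' @return a [TICNormalization-class]; the input is not modified.
#' @seealso [normFactors()], [normalized()], [filterProteotypic()]
#' @export
normalizeTotalIon <- function(x) {
    tot <- sampleTotals(x)
    if (any(tot == 0))
        stop(sprintf("sample(s) with zero total intensity: %s",
                     paste(names(tot)[tot == 0], collapse = ", ")))
    gm <- mean(tot)
    fac <- tot / gm
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x, "intensity")
    a <- sweep(a, 2L, fac[as.character(cd$sample)], `/`)
    out <- x
    SummarizedExperiment::assay(out, "intensity") <- a
    methods::new("TICNormalization", factors = fac, preTotals = tot,
                 grandMean = gm, normalized = out)
}

#' Keep only proteins identified by proteotypic peptides
#'
#' Proteins whose identification rests solely on shared (non-proteotypic)
#' peptides are discarded; the slice/sample structure is unchanged.  The
#' filter is idempotent.
#'
#' @param x a [ComplexomeExperiment-class].
#' @param ann annotation data.frame with \code{protein} and
#'   \code{proteotypic} columns; defaults to the attached annotations.
#' @return the row-subset ComplexomeExperiment.
#' @export
filterProteotypic <- function(x, ann = annotations(x)) {
    if (is.null(ann)) stop("no annotations attached or supplied")
    miss <- setdiff(rownames(x), ann$protein)
    if (length(miss))
        stop(sprintf("unannotated protein(s): %s",
                     paste(miss, collapse = ", ")))
    keep <- ann$protein[ann$proteotypic]
    x[rownames(x) %in% keep, ]
}
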