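#' Round half away from zero
#'
#' Display rounding used for report parity with printed ratio tables
#' (base \code{round()} rounds half to even, which would print 0.985 as
#' 0.98).  Computation elsewhere keeps full precision; this is applied
#' only to output columns.
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 2L) {
    s <- 10^digits
    sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Summed abundance of a protein over a scope
#'
#' Sum of (normalized) intensities over the scope's slices and all of the
#' group's replicates.  Scope \code{"all"} covers every slice of the lane;
#' a band label restricts to that band's slice(s).
#'
#' @param x a [ComplexomeExperiment-class].
#' @param group group label.
#' @param protein protein identifier.
#' @param scope \code{"all"} or a band label present in \code{bands}.
#' @param bands a [BandMap-class]; required unless scope is \code{"all"}.
#' @return nonnegative scalar.
#' @export
totalAbundance <- function(x, group, protein, scope = "all", bands = NULL) {
    slices <- if (identical(scope, "all")) seq_len(nSlices(x)) else {
        if (is.null(bands)) stop("a band scope requires a BandMap")
        bandSlices(bands, scope)
    }
    sum(vapply(samplesOf(x, group),
               function(s) sum(profileOf(x, protein, s)[slices]),
               numeric(1L)))
}

#' Median of abundance ratios
#'
#' Sorted-midpoint median with the even-n convention (mean of the two
#' central values); undefined ("nd") ratios are excluded first.
#' @param values numeric ratios, possibly containing NA for "nd".
#' @return scalar median of the defined values.
#' @export
ratioMedian <- function(values) {
    v <- values[!is.na(values)]
    if (!length(v)) stop("no defined ratios to take a median of")
    stats::median(v)
}

#' Subunit abundance ratio table for one complex
#'
#' For each member of the complex, sums the (normalized) intensities over
#' the scope's slices and all replicates of each group and forms the
#' ratio group-b / group-a (mutant over wild-type reference).  A member
#' whose scoped total is 0 in either group gets the sentinel "nd" (ratio
#' NA) and is excluded from the median.  Members absent from the matrix
#' are reported and skipped.  Ratios are computed at full precision; the
#' \code{ratio_display} column and the displayed median are rounded half
#' up to two decimals for parity with printed report tables.
#'
#' @param x a [ComplexomeExperiment-class].
#' @param catalog a [ComplexCatalog-class].
#' @param complex complex name in the catalog.
#' @param groupA reference group label (e.g. wild type).
#' @param groupB test group label (e.g. mutant).
#' @param scope \code{"all"} or a band label.
#' @param bands a [BandMap-class] when scope is a band.
#' @return list with \code{complex}, \code{scope}, \code{entries}
#'   (data.frame: protein, subunit_class, total_a, total_b, ratio,
#'   ratio_display), \code{median_ratio}, \code{median_display},
#'   \code{absent} (skipped members).
#' @export
complexRatioTable <- function(x, catalog, complex, groupA, groupB,
                              scope = "all", bands = NULL) {
    for (g in c(groupA, groupB)) samplesOf(x, g)  # validate group labels
    mem <- complexMembers(catalog, complex)
    absent <- setdiff(mem$protein, rownames(x))
    mem <- mem[mem$protein %in% rownames(x), , drop = FALSE]
    slices <- if (identical(scope, "all")) seq_len(nSlices(x)) else {
        if (is.null(bands)) stop("a band scope requires a BandMap")
        bandSlices(bands, scope)
    }
    cube <- intensityCube(x)
    d <- designTable(x)
    tot <- function(p, g) sum(cube[p, slices, d$sample[d$group == g]])
    entries <- do.call(rbind, lapply(seq_len(nrow(mem)), function(i) {
        p <- mem$protein[i]
        ta <- tot(p, groupA)
        tb <- tot(p, groupB)
        r <- if (ta == 0 || tb == 0) NA_real_ else tb / ta
        data.frame(protein = p, subunit_class = mem$subunit_class[i],
                   total_a = ta, total_b = tb, ratio = r)
    }))
    if (is.null(entries))
        entries <- data.frame(protein = character(),
                              subunit_class = character(),
                              total_a = numeric(), total_b = numeric(),
                              ratio = numeric())
    entries$ratio_display <- roundHalfUp(entries$ratio, 2L)
    med <- if (any(!is.na(entries$ratio))) ratioMedian(entries$ratio)
           else NA_real_
    if (is.na(med))
        warning(sprintf("complex '%s', scope '%s': no member detected in both groups",
                        complex, scope))
    list(complex = complex, scope = scope, entries = entries,
         median_ratio = med, median_display = roundHalfUp(med, 2L),
         absent = absent)
}

#' Band-resolved subunit ratio panel for one complex
#'
#' One [complexRatioTable()] per band, shared member order, with per-band
#' medians over the defined ("detected in both groups") entries only.
#'
#' @inheritParams complexRatioTable
#' @param bands a [BandMap-class]; all its bands are used, in order.
#' @return list with \code{tables} (named list of ratio tables),
#'   \code{medians} (named numeric), and \code{ratios} (members x bands
#'   matrix of full-precision ratios, NA = nd).
#' @export
bandRatioPanel <- function(x, catalog, complex, groupA, groupB, bands) {
    labs <- bandLabels(bands)
    tabs <- lapply(labs, function(b)
        complexRatioTable(x, catalog, complex, groupA, groupB,
                          scope = b, bands = bands))
    names(tabs) <- labs
    meds <- vapply(tabs, function(t) t$median_ratio, numeric(1L))
    mat <- vapply(tabs, function(t) t$entries$ratio,
                  numeric(nrow(tabs[[1L]]$entries)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    dimnames(mat) <- list(tabs[[1L]]$entries$protein, labs)
    list(complex = complex, tables = tabs, medians = meds, ratios = mat)
}
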