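#' Replicate-averaged migration profile of one protein in one group
#'
#' Per-slice arithmetic mean and n-1 sample standard deviation across the
#' group's replicates.  Zeros count as measured values (missing-as-zero
#' encoding); sd is 0 when the group has a single replicate.
#'
#' @param x a [ComplexomeExperiment-class].
#' @param protein protein identifier.
#' @param group group label.
#' @return list with elements \code{protein}, \code{group}, \code{mean}
#'   and \code{sd} (numeric length S) and \code{n} (replicate count).
#' @export
groupMeanProfile <- function(x, protein, group) {
    sm <- samplesOf(x, group)
    prof <- vapply(sm, function(s) profileOf(x, protein, s),
                   numeric(nSlices(x)))
    mn <- rowMeans(prof)
    sd <- if (length(sm) > 1L) apply(prof, 1L, stats::sd) else rep(0, nrow(prof))
    list(protein = protein, group = group, mean = as.numeric(mn),
         sd = as.numeric(sd), n = length(sm))
}

#' Replicate-averaged profiles for all proteins of a group
#'
#' @inheritParams groupMeanProfile
#' @return list with matrices \code{mean} and \code{sd} (proteins x S) and
#'   \code{n}.
#' @export
groupProfiles <- function(x, group) {
    sm <- samplesOf(x, group)
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x, "intensity")
    S <- nSlices(x)
    cube <- vapply(sm, function(s) {
        j <- which(cd$sample == s)
        a[, j[order(cd$slice[j])], drop = FALSE]
    }, matrix(0, nrow(x), S))
    mn <- apply(cube, c(1L, 2L), mean)
    sd <- if (length(sm) > 1L) apply(cube, c(1L, 2L), stats::sd)
          else matrix(0, nrow(x), S)
    dimnames(mn) <- dimnames(sd) <- list(rownames(x), NULL)
    list(mean = mn, sd = sd, n = length(sm))
}

#' Scale a migration profile to its highest slice
#'
#' Divides by the maximum so the peak slice is exactly 1; an all-zero
#' profile is returned unchanged.  Idempotent.
#' @param v nonnegative numeric vector (per-slice intensities).
#' @return numeric vector of the same length.
#' @export
maxScale <- function(v) {
    m <- max(v)
    if (m > 0) v / m else v
}

#' Number of replicates in which a protein was detected
#'
#' A protein counts as detected in a replicate when its summed intensity
#' over all S slices is greater than zero.
#' @inheritParams groupMeanProfile
#' @return integer in 0..n_replicates.
#' @export
detectionCount <- function(x, protein, group) {
    sm <- samplesOf(x, group)
    sum(vapply(sm, function(s) sum(profileOf(x, protein, s)) > 0, logical(1L)))
}

#' Deterministic clustering order of migration profiles
#'
#' Agglomerative clustering (average linkage, Euclidean metric) of
#' max-scaled profiles; returns the dendrogram leaf order for heat-map row
#' ordering.  Ties are broken by input order (the order of
#' \code{rownames(profiles)}), so the result is permutation-invariant up
#' to that tie-break.
#'
#' @param profiles numeric matrix, proteins x slices; rows are max-scaled
#'   internally.
#' @return character vector of protein ids in leaf order.
#' @export
clusterOrder <- function(profiles) {
    if (is.null(rownames(profiles)))
        stop("'profiles' must have protein rownames")
    if (nrow(profiles) == 1L) return(rownames(profiles))
    scaled <- t(apply(profiles, 1L, maxScale))
    h <- stats::hclust(stats::dist(scaled, method = "euclidean"),
                       method = "average")
    rownames(profiles)[h$order]
}
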