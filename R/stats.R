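#' Welch's two-sample t-test
#'
#' Textbook Welch statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value from the t distribution.  Conventions for
#' degenerate inputs: when both groups have zero variance the statistic is
#' 0 and p = 1 if the means are equal, and the p-value is 0 (|t| infinite,
#' df = n_a + n_b - 2) if they differ.
#'
#' @param a,b numeric vectors of per-replicate values (>= 2 each).
#' @return list with \code{t}, \code{df}, \code{p} and the group means.
#' @export
welchTest <- function(a, b) {
    na <- length(a); nb <- length(b)
    if (na < 2L || nb < 2L) stop("each group needs >= 2 replicates")
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / na + vb / nb
    d <- mean(a) - mean(b)
    if (se2 == 0) {
        t <- if (d == 0) 0 else sign(d) * Inf
        df <- na + nb - 2
        p <- if (d == 0) 1 else 0
    } else {
        t <- d / sqrt(se2)
        df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
        p <- 2 * stats::pt(-abs(t), df)
    }
    list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b))
}

#' Welch test on whole-lane protein abundances
#'
#' For one protein, sums all S normalized slice intensities per replicate
#' and tests the group-a sums against the group-b sums with [welchTest()].
#'
#' @param x a [ComplexomeExperiment-class] (normalized intensities).
#' @param protein protein identifier.
#' @param groupA,groupB group labels (reference first).
#' @return list with the per-replicate sums (\code{sums_a}, \code{sums_b})
#'   and \code{t}, \code{df}, \code{p}.
#' @export
welchAbundanceTest <- function(x, protein, groupA, groupB) {
    sa <- vapply(samplesOf(x, groupA),
                 function(s) sum(profileOf(x, protein, s)), numeric(1L))
    sb <- vapply(samplesOf(x, groupB),
                 function(s) sum(profileOf(x, protein, s)), numeric(1L))
    w <- welchTest(sa, sb)
    c(list(protein = protein, sums_a = sa, sums_b = sb), w)
}

#' Amplitude-adjusted Euclidean profile distance
#'
#' Euclidean distance between two group-mean migration profiles, divided
#' by the maximal mean intensity of either profile to remove
#' amplitude-introduced bias: \code{d = ||a - b|| / max(max(a), max(b))}.
#' The distance is 0 iff the profiles are identical, symmetric, and
#' invariant under a common positive rescaling of both profiles.
#'
#' @param a,b nonnegative numeric vectors of equal length (not both
#'   all-zero).
#' @return nonnegative scalar.
#' @export
amplitudeAdjustedDistance <- function(a, b) {
    if (length(a) != length(b)) stop("profiles differ in length")
    m <- max(max(a), max(b))
    if (m == 0) stop("distance undefined for two all-zero profiles")
    sqrt(sum((a - b)^2)) / m
}

#' Per-protein differential table between two groups
#'
#' For every protein: per-replicate whole-lane sums, Welch t/df/p on the
#' sums, the amplitude-adjusted distance between the two group-mean
#' profiles (NA when the protein is undetected in both groups), and a
#' Benjamini-Hochberg adjusted p-value column (an extension; the raw
#' p-values are the primary output).
#'
#' @param x a [ComplexomeExperiment-class] (normalized intensities).
#' @param groupA,groupB group labels (reference first).
#' @return data.frame, one row per protein: protein, mean_sum_a,
#'   mean_sum_b, t, df, p, distance, p_bh.
#' @export
differentialTable <- function(x, groupA, groupB) {
    pa <- groupProfiles(x, groupA)
    pb <- groupProfiles(x, groupB)
    cube <- intensityCube(x)
    d <- designTable(x)
    sums <- apply(cube, c(1L, 3L), sum)           # protein x sample
    ia <- d$sample[d$group == groupA]
    ib <- d$sample[d$group == groupB]
    res <- lapply(rownames(x), function(p) {
        w <- welchTest(sums[p, ia], sums[p, ib])
        ma <- pa$mean[p, ]; mb <- pb$mean[p, ]
        dist <- if (max(ma, mb) == 0) NA_real_
                else amplitudeAdjustedDistance(ma, mb)
        data.frame(protein = p, mean_sum_a = w$mean_a, mean_sum_b = w$mean_b,
                   t = w$t, df = w$df, p = w$p, distance = dist)
    })
    out <- do.call(rbind, res)
    out$p_bh <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}
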