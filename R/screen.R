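#' Consensus migration profile of a set of canonical subunits
#'
#' Mean of the max-scaled group-mean profiles of the given members —
#' the reference shape that co-migration candidates are compared with.
#' Members undetected in the group (all-zero mean profile) are excluded
#' and reported.
#'
#' @param x a [ComplexomeExperiment-class].
#' @param group group label.
#' @param members character vector of member protein ids.
#' @return list with \code{group}, \code{members} (those used),
#'   \code{excluded}, and \code{consensus} (numeric length S, entries in
#'   [0, 1]).
#' @export
consensusProfile <- function(x, group, members) {
    if (!length(members)) stop("empty member set")
    miss <- setdiff(members, rownames(x))
    if (length(miss))
        stop(sprintf("member(s) absent from matrix: %s",
                     paste(miss, collapse = ", ")))
    prof <- vapply(members, function(p) groupMeanProfile(x, p, group)$mean,
                   numeric(nSlices(x)))
    detected <- colSums(prof) > 0
    if (!any(detected))
        stop(sprintf("no member detected in group '%s'", group))
    scaled <- apply(prof[, detected, drop = FALSE], 2L, maxScale)
    list(group = group, members = members[detected],
         excluded = members[!detected],
         consensus = as.numeric(rowMeans(scaled)))
}

#' Similarity of a migration profile to a consensus
#'
#' Pearson correlation between the max-scaled candidate profile and the
#' consensus, in [-1, 1].  When either vector is constant the correlation
#' is undefined and the similarity is 0 by convention; an all-zero
#' candidate is an error.
#'
#' @param candidate nonnegative numeric vector (per-slice intensities).
#' @param consensus numeric vector of the same length.
#' @return scalar in [-1, 1].
#' @export
profileSimilarity <- function(candidate, consensus) {
    if (length(candidate) != length(consensus))
        stop("profiles differ in length")
    if (max(candidate) == 0) stop("all-zero candidate profile")
    a <- maxScale(candidate)
    if (stats::sd(a) == 0 || stats::sd(consensus) == 0) return(0)
    stats::cor(a, consensus)
}

.detectionMatrix <- function(x) {
    cube <- intensityCube(x)
    d <- designTable(x)
    sums <- apply(cube, c(1L, 3L), sum)           # protein x sample
    out <- vapply(unique(d$group), function(g)
        rowSums(sums[, d$sample[d$group == g], drop = FALSE] > 0),
        numeric(nrow(cube)))
    dimnames(out) <- list(rownames(cube), unique(d$group))
    out
}

.screenAnnotations <- function(x, ann) {
    if (is.null(ann)) stop("screening requires protein annotations")
    ann <- .checkAnnotations(ann)
    miss <- setdiff(rownames(x), ann$protein)
    if (length(miss))
        stop(sprintf("unannotated protein(s): %s",
                     paste(miss, collapse = ", ")))
    ann[match(rownames(x), ann$protein), ]
}

#' Four-criterion co-migration screen for complex-associated proteins
#'
#' Screens every non-member protein for (i) a migration profile
#' resembling the members' consensus in BOTH groups (Pearson similarity
#' of max-scaled profiles >= \code{minSimilarity}), (ii) detection in at
#' least \code{minReplicates} replicates of at least one group, (iii) a
#' predicted chloroplast transit peptide, and (iv) conservation in
#' photosynthetic organisms.  Criteria (iii) and (iv) are consumed as
#' boolean annotations.
#'
#' @param x a [ComplexomeExperiment-class] (normalized intensities).
#' @param members canonical subunit ids defining the consensus; excluded
#'   from candidacy.
#' @param groupA,groupB the two group labels.
#' @param minSimilarity similarity threshold, required in both groups
#'   (default 0.8).
#' @param minReplicates detection threshold, required in at least one
#'   group (default 2).
#' @param ann annotations (default: attached).
#' @return list with \code{candidates} (passing proteins sorted by
#'   \code{min(similarity_a, similarity_b)} descending, ties by protein
#'   id) and \code{diagnostics} (every screened protein with per-criterion
#'   booleans and a failure-reason string).
#' @export
screenComigrating <- function(x, members, groupA, groupB,
                              minSimilarity = 0.8, minReplicates = 2L,
                              ann = annotations(x)) {
    ann <- .screenAnnotations(x, ann)
    consA <- consensusProfile(x, groupA, members)
    consB <- consensusProfile(x, groupB, members)
    gpA <- groupProfiles(x, groupA)
    gpB <- groupProfiles(x, groupB)
    det <- .detectionMatrix(x)
    cand <- sort(setdiff(rownames(x), members))
    rows <- lapply(cand, function(p) {
        ma <- gpA$mean[p, ]
        mb <- gpB$mean[p, ]
        simA <- if (max(ma) > 0) profileSimilarity(ma, consA$consensus)
                else NA_real_
        simB <- if (max(mb) > 0) profileSimilarity(mb, consB$consensus)
                else NA_real_
        da <- det[p, groupA]
        db <- det[p, groupB]
        i <- !is.na(simA) && !is.na(simB) &&
             simA >= minSimilarity && simB >= minSimilarity
        ii <- max(da, db) >= minReplicates
        a <- ann[ann$protein == p, ]
        data.frame(protein = p, similarity_a = simA, similarity_b = simB,
                   detection_a = da, detection_b = db,
                   has_ctp = a$has_ctp, conserved = a$conserved,
                   crit_i = i, crit_ii = ii, crit_iii = a$has_ctp,
                   crit_iv = a$conserved,
                   passes = i && ii && a$has_ctp && a$conserved)
    })
    diag <- do.call(rbind, rows)
    diag$failure <- apply(diag[, c("crit_i", "crit_ii", "crit_iii",
                                   "crit_iv")], 1L, function(v) {
        f <- c("criterion i", "criterion ii", "criterion iii",
               "criterion iv")[!v]
        if (length(f)) paste(f, collapse = "; ") else ""
    })
    hits <- diag[diag$passes, , drop = FALSE]
    score <- pmin(hits$similarity_a, hits$similarity_b)
    hits <- hits[order(-score, hits$protein), , drop = FALSE]
    rownames(hits) <- rownames(diag) <- NULL
    list(candidates = hits, diagnostics = diag,
         consensus_a = consA, consensus_b = consB)
}

#' Band-enrichment screen (RC47-style)
#'
#' Finds proteins that accumulate in one gel band of the test group at
#' much higher levels than in the reference group and meet the
#' detection/transit-peptide/conservation criteria (ii)-(iv) of
#' [screenComigrating()].  The fold is the band total of group B over the
#' band total of group A; when the reference total is 0 but the test
#' total is positive the fold is Inf ("nd" in the reference) and always
#' passes the fold gate.
#'
#' @inheritParams screenComigrating
#' @param band band label to test for enrichment.
#' @param bands a [BandMap-class].
#' @param minFold fold threshold (> 1; default 4).
#' @return list with \code{candidates} (sorted by band fold descending,
#'   ties by protein id) and \code{diagnostics}.
#' @export
screenBandEnriched <- function(x, band, bands, groupA, groupB,
                               minFold = 4, minReplicates = 2L,
                               ann = annotations(x)) {
    if (minFold <= 1) stop("minFold must exceed 1")
    ann <- .screenAnnotations(x, ann)
    slices <- bandSlices(bands, band)  # validates the band label
    cube <- intensityCube(x)
    d <- designTable(x)
    det <- .detectionMatrix(x)
    for (g in c(groupA, groupB)) samplesOf(x, g)
    rows <- lapply(sort(rownames(x)), function(p) {
        ta <- sum(cube[p, slices, d$sample[d$group == groupA]])
        tb <- sum(cube[p, slices, d$sample[d$group == groupB]])
        fold <- if (ta == 0 && tb == 0) NA_real_
                else if (ta == 0) Inf else tb / ta
        da <- det[p, groupA]
        db <- det[p, groupB]
        ii <- max(da, db) >= minReplicates
        a <- ann[ann$protein == p, ]
        foldpass <- !is.na(fold) && fold >= minFold
        data.frame(protein = p, band_total_a = ta, band_total_b = tb,
                   band_fold = fold, detection_a = da, detection_b = db,
                   has_ctp = a$has_ctp, conserved = a$conserved,
                   crit_fold = foldpass, crit_ii = ii, crit_iii = a$has_ctp,
                   crit_iv = a$conserved,
                   passes = foldpass && ii && a$has_ctp && a$conserved)
    })
    diag <- do.call(rbind, rows)
    diag$failure <- apply(diag[, c("crit_fold", "crit_ii", "crit_iii",
                                   "crit_iv")], 1L, function(v) {
        f <- c("fold gate", "criterion ii", "criterion iii",
               "criterion iv")[!v]
        if (length(f)) paste(f, collapse = "; ") else ""
    })
    hits <- diag[diag$passes, , drop = FALSE]
    hits <- hits[order(-hits$band_fold, hits$protein), , drop = FALSE]
    rownames(hits) <- rownames(diag) <- NULL
    list(candidates = hits, diagnostics = diag, band = band)
}
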