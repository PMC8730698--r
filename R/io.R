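#' Read a slice-resolved intensity table
#'
#' Two tab-separated dialects are supported. The \code{"wide"} dialect has
#' one row per protein, a first column \code{protein}, and one column per
#' (sample, slice) pair named \code{"<sample>|slice<k>"}; blank cells are
#' read as 0.  The \code{"mapped"} dialect consumes an arbitrary wide
#' export (for example, per-slice sample columns of a proteinGroups-style
#' table) through a user-supplied column-mapping file with columns
#' \code{column}, \code{sample}, \code{slice}.
#'
#' @param path path to the intensity TSV (UTF-8, Unix newlines).
#' @param dialect \code{"wide"} (default) or \code{"mapped"}.
#' @param mapping path to the column-mapping TSV (dialect \code{"mapped"}).
#' @param design optional [sampleDesign()]; when NULL, sample names of the
#'   form \code{"<group>_<replicate>"} are parsed, otherwise each sample
#'   becomes its own group with replicate 1.
#' @param idColumn name of the protein identifier column (dialect
#'   \code{"mapped"}; default \code{"protein"}).
#' @return a [ComplexomeExperiment-class].
#' @export
readIntensityTable <- function(path, dialect = c("wide", "mapped"),
                               mapping = NULL, design = NULL,
                               idColumn = "protein") {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (dialect == "wide") {
        if (!"protein" %in% colnames(tab))
            stop("malformed header: no 'protein' column")
        valcols <- setdiff(colnames(tab), "protein")
        m <- regmatches(valcols, regexec("^(.*)\\|slice([0-9]+)$", valcols))
        bad <- valcols[vapply(m, length, 1L) != 3L]
        if (length(bad))
            stop(sprintf("malformed header: column '%s' is not '<sample>|slice<k>'",
                         bad[[1L]]))
        map <- data.frame(column = valcols,
                          sample = vapply(m, `[`, "", 2L),
                          slice = as.integer(vapply(m, `[`, "", 3L)))
    } else {
        if (is.null(mapping)) stop("dialect 'mapped' requires a mapping file")
        map <- utils::read.delim(mapping, stringsAsFactors = FALSE)
        need <- c("column", "sample", "slice")
        if (!all(need %in% colnames(map)))
            stop(sprintf("mapping file needs columns: %s",
                         paste(need, collapse = ", ")))
        miss <- setdiff(map$column, colnames(tab))
        if (length(miss))
            stop(sprintf("mapped column(s) absent from table: %s",
                         paste(miss, collapse = ", ")))
        if (!idColumn %in% colnames(tab))
            stop(sprintf("malformed header: no '%s' column", idColumn))
        tab$protein <- tab[[idColumn]]
        map$slice <- as.integer(map$slice)
    }
    if (anyDuplicated(map[, c("sample", "slice")]))
        stop("duplicate (sample, slice) column assignment")
    cnt <- tapply(map$slice, map$sample, function(k) length(unique(k)))
    if (length(unique(cnt)) != 1L)
        stop(sprintf("samples disagree on slice count: %s",
                     paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
    S <- unique(cnt)[[1L]]
    samples <- unique(map$sample)
    if (anyDuplicated(tab$protein)) stop("duplicate protein identifiers")
    proteins <- as.character(tab$protein)
    cube <- array(0, dim = c(length(proteins), S, length(samples)),
                  dimnames = list(proteins, NULL, samples))
    for (i in seq_len(nrow(map))) {
        v <- tab[[map$column[i]]]
        if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "", "0", v)))
        v[is.na(v)] <- 0
        if (any(v < 0))
            stop(sprintf("negative intensity in column '%s'", map$column[i]))
        cube[, map$slice[i], map$sample[i]] <- v
    }
    if (is.null(design)) design <- .inferDesign(samples)
    ComplexomeExperiment(cube, design)
}

.inferDesign <- function(samples) {
    m <- regmatches(samples, regexec("^(.*)_([0-9]+)$", samples))
    ok <- vapply(m, length, 1L) == 3L
    if (all(ok))
        sampleDesign(samples, vapply(m, `[`, "", 2L),
                     as.integer(vapply(m, `[`, "", 3L)))
    else
        sampleDesign(samples, samples, rep(1L, length(samples)))
}

#' Write a ComplexomeExperiment in the wide intensity dialect
#'
#' Inverse of [readIntensityTable()] (dialect \code{"wide"}).
#' @param x a ComplexomeExperiment.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeIntensityTable <- function(x, path) {
    a <- SummarizedExperiment::assay(x, "intensity")
    out <- data.frame(protein = rownames(x), check.names = FALSE)
    out <- cbind(out, as.data.frame(a, check.names = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write protein annotation tables
#'
#' Tab-separated, columns \code{protein}, \code{description},
#' \code{proteotypic}, \code{has_ctp}, \code{conserved}, \code{complex},
#' \code{subunit_class}.  Booleans are encoded 0/1 (or TRUE/FALSE); any
#' other encoding is rejected.  Empty \code{complex}/\code{subunit_class}
#' fields read as unset (NA).
#'
#' @param path TSV path.
#' @return data.frame with typed columns, one row per protein.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("protein", "proteotypic", "has_ctp", "conserved")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop(sprintf("annotation table lacks column(s): %s",
                     paste(miss, collapse = ", ")))
    for (cc in c("proteotypic", "has_ctp", "conserved")) {
        v <- tab[[cc]]
        ok <- v %in% c("0", "1", "TRUE", "FALSE")
        if (!all(ok))
            stop(sprintf("column '%s': unknown boolean encoding '%s'",
                         cc, v[!ok][[1L]]))
        tab[[cc]] <- v %in% c("1", "TRUE")
    }
    if (is.null(tab$description)) tab$description <- ""
    for (cc in c("complex", "subunit_class")) {
        if (is.null(tab[[cc]])) tab[[cc]] <- NA_character_
        tab[[cc]][tab[[cc]] == ""] <- NA_character_
    }
    .checkAnnotations(tab[, c("protein", "description", "proteotypic",
                              "has_ctp", "conserved", "complex",
                              "subunit_class")])
}

#' @rdname readAnnotations
#' @param ann annotation data.frame.
#' @export
writeAnnotations <- function(ann, path) {
    ann <- .checkAnnotations(ann)
    out <- ann[, c("protein", "description", "proteotypic", "has_ctp",
                   "conserved", "complex", "subunit_class")]
    for (cc in c("proteotypic", "has_ctp", "conserved"))
        out[[cc]] <- as.integer(out[[cc]])
    for (cc in c("complex", "subunit_class"))
        out[[cc]][is.na(out[[cc]])] <- ""
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write a band map
#'
#' TSV with columns \code{band} and \code{slices} (comma-separated slice
#' indices, e.g. \code{"4"} or \code{"21,22"}).
#' @param path TSV path.
#' @return a [BandMap-class].
#' @export
readBandMap <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("band", "slices") %in% colnames(tab)))
        stop("band map needs columns 'band' and 'slices'")
    b <- lapply(strsplit(tab$slices, ","), function(v) as.integer(trimws(v)))
    names(b) <- tab$band
    bandMap(b)
}

#' @rdname readBandMap
#' @param x a BandMap.
#' @export
writeBandMap <- function(x, path) {
    tab <- data.frame(band = bandLabels(x),
                      slices = vapply(x@bands, paste, "", collapse = ","))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write a complex catalog
#'
#' TSV with columns \code{complex}, \code{protein}, \code{subunit_class},
#' one row per member; member order is preserved.
#' @param path TSV path.
#' @return a [ComplexCatalog-class].
#' @export
readComplexCatalog <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    complexCatalog(tab)
}

#' @rdname readComplexCatalog
#' @param x a ComplexCatalog.
#' @export
writeComplexCatalog <- function(x, path) {
    utils::write.table(x@members, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Cross-check matrix, annotations, catalog and band map
#'
#' Report-only consistency check: lists matrix proteins lacking an
#' annotation, catalog members absent from the matrix, and band slices out
#' of the matrix slice range.  The report is empty iff the bundle is fully
#' consistent.
#'
#' @param x a ComplexomeExperiment.
#' @param ann annotation data.frame (default: the attached annotations).
#' @param catalog optional [ComplexCatalog-class].
#' @param bands optional [BandMap-class].
#' @return data.frame with columns \code{category}, \code{item},
#'   \code{message}; zero rows when consistent.
#' @export
validateBundle <- function(x, ann = annotations(x), catalog = NULL,
                           bands = NULL) {
    rep <- data.frame(category = character(), item = character(),
                      message = character())
    add <- function(category, item, message)
        rbind(rep, data.frame(category = category, item = item,
                              message = message))
    if (!is.null(ann)) {
        for (p in setdiff(rownames(x), ann$protein))
            rep <- add("missing_annotation", p,
                       sprintf("protein '%s' has no annotation", p))
    }
    if (!is.null(catalog)) {
        for (p in setdiff(catalog@members$protein, rownames(x)))
            rep <- add("missing_member", p,
                       sprintf("catalog member '%s' absent from matrix", p))
        if (!is.null(ann)) {
            bad <- setdiff(stats::na.omit(unique(ann$complex)),
                           complexNames(catalog))
            for (cx in bad)
                rep <- add("unknown_complex", cx,
                           sprintf("annotated complex '%s' not in catalog", cx))
        }
    }
    if (!is.null(bands)) {
        S <- nSlices(x)
        for (b in bandLabels(bands)) {
            k <- bandSlices(bands, b)
            if (any(k > S))
                rep <- add("band_out_of_range", b,
                           sprintf("band '%s' uses slice %d but S=%d",
                                   b, max(k), S))
        }
    }
    rep
}
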