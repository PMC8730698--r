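#' Pipeline configuration
#'
#' Validates and assembles the configuration of [runFullPipeline()].
#' Inputs may be given as file paths (read with the package readers) or
#' as in-memory objects.
#'
#' @param intensity intensity TSV path or a [ComplexomeExperiment-class].
#' @param annotations annotation TSV path or data.frame; optional when
#'   already attached to \code{intensity}.
#' @param catalog complex catalog TSV path or [ComplexCatalog-class]
#'   (optional; enables ratio tables).
#' @param bands band map TSV path or [BandMap-class] (optional; enables
#'   band panels and the band screen).
#' @param groupA,groupB reference and test group labels.
#' @param outdir output directory (created if absent).
#' @param minSimilarity,minFold,minReplicates screen thresholds (see
#'   [screenComigrating()], [screenBandEnriched()]).
#' @param screenMembers member ids (or a catalog complex name) defining
#'   the co-migration consensus; NULL disables that screen.
#' @param screenBand band label for the enrichment screen; NULL disables.
#' @param verbose log progress to standard error.
#' @return validated config list for [runFullPipeline()].
#' @export
pipelineConfig <- function(intensity, annotations = NULL, catalog = NULL,
                           bands = NULL, groupA, groupB, outdir,
                           minSimilarity = 0.8, minFold = 4,
                           minReplicates = 2L, screenMembers = NULL,
                           screenBand = NULL, verbose = TRUE) {
    for (arg in c("intensity", "annotations", "catalog", "bands")) {
        v <- get(arg)
        if (is.character(v) && !file.exists(v))
            stop(sprintf("[config] %s file does not exist: %s", arg, v))
    }
    if (minSimilarity < -1 || minSimilarity > 1)
        stop("[config] minSimilarity must be in [-1, 1]")
    if (minFold <= 1) stop("[config] minFold must exceed 1")
    if (minReplicates < 1) stop("[config] minReplicates must be >= 1")
    list(intensity = intensity, annotations = annotations,
         catalog = catalog, bands = bands, groupA = groupA,
         groupB = groupB, outdir = outdir, minSimilarity = minSimilarity,
         minFold = minFold, minReplicates = as.integer(minReplicates),
         screenMembers = screenMembers, screenBand = screenBand,
         verbose = isTRUE(verbose))
}

.stage <- function(cfg, stage, expr) {
    if (cfg$verbose)
        message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
}

.writeTsv <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full complexome analysis pipeline
#'
#' Orchestrates the stages in analysis order: total-ion normalization,
#' proteotypic filter, replicate-averaged profiles, Welch/differential
#' statistics, complex ratio tables (whole-lane plus band panel), the
#' screens, and a clustered heat map.  All tabular outputs carry full
#' precision plus a \code{*_display} column rounded half-up to two
#' decimals.  A manifest (JSON) records parameters, input checksums and
#' output files; re-running with the same inputs reproduces all numeric
#' outputs byte-identically.  Any stage error aborts with a stage-named
#' message.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runFullPipeline <- function(config) {
    cfg <- config
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    checksums <- list()
    x <- .stage(cfg, "load", {
        if (is.character(cfg$intensity)) {
            checksums$intensity <- unname(tools::md5sum(cfg$intensity))
            readIntensityTable(cfg$intensity)
        } else cfg$intensity
    })
    ann <- .stage(cfg, "annotations", {
        if (is.character(cfg$annotations)) {
            checksums$annotations <- unname(tools::md5sum(cfg$annotations))
            readAnnotations(cfg$annotations)
        } else if (!is.null(cfg$annotations)) cfg$annotations
        else annotations(x)
    })
    if (is.null(ann)) stop("stage 'annotations' failed: no annotations given")
    catalog <- if (is.character(cfg$catalog)) {
        checksums$catalog <- unname(tools::md5sum(cfg$catalog))
        readComplexCatalog(cfg$catalog)
    } else cfg$catalog
    bands <- if (is.character(cfg$bands)) {
        checksums$bands <- unname(tools::md5sum(cfg$bands))
        readBandMap(cfg$bands)
    } else cfg$bands
    outputs <- character()
    out <- function(name) {
        p <- file.path(cfg$outdir, name)
        outputs <<- c(outputs, p)
        p
    }

    norm <- .stage(cfg, "normalize", normalizeTotalIon(x))
    nx <- normalized(norm)
    annotations(nx) <- ann
    .writeTsv(data.frame(sample = names(normFactors(norm)),
                         pre_total = norm@preTotals,
                         factor = normFactors(norm)), out("factors.tsv"))
    writeIntensityTable(nx, out("normalized.tsv"))
    nx <- .stage(cfg, "proteotypic_filter", filterProteotypic(nx))

    prof <- .stage(cfg, "profiles", {
        long <- do.call(rbind, lapply(groupLabels(nx), function(g) {
            gp <- groupProfiles(nx, g)
            data.frame(protein = rep(rownames(nx), ncol(gp$mean)),
                       group = g,
                       slice = rep(seq_len(ncol(gp$mean)),
                                   each = nrow(nx)),
                       mean = as.numeric(gp$mean),
                       sd = as.numeric(gp$sd))
        }))
        .writeTsv(long[order(long$protein, long$group, long$slice), ],
                  out("profiles.tsv"))
        long
    })

    diff <- .stage(cfg, "differential",
                   differentialTable(nx, cfg$groupA, cfg$groupB))
    diff$distance_display <- roundHalfUp(diff$distance, 2L)
    .writeTsv(diff, out("differential.tsv"))

    ratios <- NULL
    if (!is.null(catalog)) ratios <- .stage(cfg, "ratio_tables", {
        res <- list()
        for (cx in complexNames(catalog)) {
            tab <- complexRatioTable(nx, catalog, cx, cfg$groupA,
                                     cfg$groupB)
            ent <- tab$entries
            ent <- rbind(ent, data.frame(
                protein = "Median", subunit_class = "",
                total_a = NA, total_b = NA, ratio = tab$median_ratio,
                ratio_display = tab$median_display))
            .writeTsv(ent, out(sprintf("ratios_%s.tsv", cx)))
            res[[cx]] <- tab
            if (!is.null(bands)) {
                pan <- bandRatioPanel(nx, catalog, cx, cfg$groupA,
                                      cfg$groupB, bands)
                wide <- as.data.frame(pan$ratios)
                wide <- cbind(protein = rownames(wide), wide)
                wide <- rbind(wide, c(protein = "Median",
                                      as.list(pan$medians)))
                .writeTsv(wide, out(sprintf("band_ratios_%s.tsv", cx)))
                res[[paste0(cx, "_bands")]] <- pan
            }
        }
        res
    })

    screens <- list()
    if (!is.null(cfg$screenMembers)) {
        members <- cfg$screenMembers
        if (length(members) == 1L && !is.null(catalog) &&
            members %in% complexNames(catalog))
            members <- complexMembers(catalog, members)$protein
        screens$comigration <- .stage(cfg, "comigration_screen", {
            sc <- screenComigrating(nx, members, cfg$groupA, cfg$groupB,
                                    cfg$minSimilarity, cfg$minReplicates)
            .writeTsv(sc$candidates, out("screen_comigration.tsv"))
            .writeTsv(sc$diagnostics,
                      out("screen_comigration_diagnostics.tsv"))
            sc
        })
    }
    if (!is.null(cfg$screenBand) && !is.null(bands)) {
        screens$band <- .stage(cfg, "band_screen", {
            sc <- screenBandEnriched(nx, cfg$screenBand, bands,
                                     cfg$groupA, cfg$groupB, cfg$minFold,
                                     cfg$minReplicates)
            .writeTsv(sc$candidates, out("screen_band.tsv"))
            .writeTsv(sc$diagnostics, out("screen_band_diagnostics.tsv"))
            sc
        })
    }

    .stage(cfg, "heatmap", {
        gp <- groupProfiles(nx, cfg$groupA)
        ord <- clusterOrder(gp$mean)
        renderHeatmap(gp$mean, ord, out("heatmap.png"))
        outputs <- c(outputs, paste0(file.path(cfg$outdir, "heatmap.png"),
                                     ".tsv"))
    })

    manifest <- list(
        package = "complexomics",
        version = as.character(utils::packageVersion("complexomics")),
        parameters = cfg[c("groupA", "groupB", "minSimilarity", "minFold",
                           "minReplicates", "screenBand")],
        screen_members = cfg$screenMembers,
        input_checksums = checksums,
        n_proteins = nrow(nx), n_slices = nSlices(nx),
        samples = designTable(nx), outputs = basename(outputs))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(manifest,
                list(normalization = norm, differential = diff,
                     ratios = ratios, screens = screens)))
}

#' Render a migration-profile heat map
#'
#' One row per protein in the given order, one column per slice, each row
#' max-scaled (normalized to the gel slice with highest intensities).
#' The exact plotted matrix is written alongside as
#' \code{<path>.tsv}.
#'
#' @param profiles numeric matrix, proteins x slices, with protein
#'   rownames.
#' @param order character vector of protein ids giving the row order
#'   (default: input order).
#' @param path output image path (PNG).
#' @return invisibly, the max-scaled plotted matrix.
#' @export
renderHeatmap <- function(profiles, order = rownames(profiles), path) {
    if (!nrow(profiles)) stop("no profiles to render")
    scaled <- t(apply(profiles[order, , drop = FALSE], 1L, maxScale))
    rownames(scaled) <- order
    colnames(scaled) <- seq_len(ncol(scaled))
    sidecar <- cbind(data.frame(protein = rownames(scaled)),
                     as.data.frame(scaled))
    .writeTsv(sidecar, paste0(path, ".tsv"))
    pheatmap::pheatmap(scaled, cluster_rows = FALSE, cluster_cols = FALSE,
                       filename = path, silent = TRUE,
                       fontsize_row = 6, legend = TRUE)
    invisible(scaled)
}
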