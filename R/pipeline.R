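# End-to-end pipeline: normalization -> segmentation -> union analysis
# volume -> hotspot extraction -> pairwise concordance reports.
#
# Registration and resampling are an explicit precondition, not a stage:
# the pipeline refuses non-matching grids rather than silently
# resampling. T2 participates only in analysis-volume construction,
# never in correlations or hotspots.

.PAIRS <- list(
    TBR_GE180_vs_rCE = c(y = "TBR_GE180", x = "rCE"),
    TBR_FET_vs_rCE = c(y = "TBR_FET", x = "rCE"),
    TBR_GE180_vs_TBR_FET = c(y = "TBR_GE180", x = "TBR_FET"))

.asVolume <- function(x) {
    if (is.character(x)) readVolume(x)
    else if (is(x, "VoxelGrid")) x
    else stop("expected a VoxelGrid or a NIfTI path")
}

.asMask <- function(x) {
    if (is.character(x)) readMask(x)
    else if (is(x, "MaskVolume")) x
    else stop("expected a MaskVolume or a NIfTI path")
}

#' Assemble a pipeline run configuration
#'
#' Volumes and masks may be given as in-memory objects or NIfTI paths;
#' everything is read and grid-checked here, so [runPipeline()] starts
#' from a fully resolved configuration.
#'
#' @param petTspo,petAa static PET uptake volumes (TSPO and amino-acid
#'   tracer), [VoxelGrid-class] or path.
#' @param t1Native,t1CE pre- and post-contrast T1-weighted MRI.
#' @param t2 optional T2-weighted MRI.
#' @param petBackground contralesional background VOI for PET
#'   normalization (crescent-shaped in clinical practice).
#' @param mriBackground contralesional white-matter VOI for MRI
#'   normalization.
#' @param confine optional confining mask for region growing; defaults
#'   to the whole grid minus both background VOIs.
#' @param thresholds named numeric overriding [defaultThreshold()] per
#'   modality tag.
#' @param hotspotDiameterMm equivalent-sphere diameter for the hotspot
#'   voxel count (default 10 mm).
#' @param connectivity "face" or "full".
#' @param includeT2 whether a TBR_T2 segmentation joins the analysis
#'   volume.
#' @param seeds named list of explicit seed index matrices per modality
#'   tag; missing entries use [autoSeeds()].
#' @return A [RunConfig-class].
#' @export
runConfig <- function(petTspo, petAa, t1Native, t1CE, t2 = NULL,
                      petBackground, mriBackground, confine = NULL,
                      thresholds = c(),
                      hotspotDiameterMm = 10,
                      connectivity = c("face", "full"),
                      includeT2 = !is.null(t2),
                      seeds = list()) {
    connectivity <- match.arg(connectivity)
    volumes <- list(pet_tspo = .asVolume(petTspo),
                    pet_aa = .asVolume(petAa),
                    t1_native = .asVolume(t1Native),
                    t1_ce = .asVolume(t1CE))
    if (!is.null(t2)) volumes$t2 <- .asVolume(t2)
    if (includeT2 && is.null(volumes$t2))
        stop("includeT2 = TRUE but no T2 volume was supplied")
    masks <- list(petBackground = .asMask(petBackground),
                  mriBackground = .asMask(mriBackground))
    if (!is.null(confine)) masks$confine <- .asMask(confine)

    ref <- volumes[[1L]]
    for (nm in names(volumes)[-1L])
        .checkSameGrid(ref, volumes[[nm]], "pet_tspo", nm)
    for (nm in names(masks))
        .checkSameGrid(ref, masks[[nm]], "pet_tspo", nm)

    thr <- .MODALITY_THRESHOLDS
    thr[names(thresholds)] <- thresholds
    if (any(thr <= 0)) stop("all thresholds must be positive")

    new("RunConfig", volumes = volumes, masks = masks, thresholds = thr,
        hotspotDiameterMm = as.numeric(hotspotDiameterMm),
        connectivity = connectivity, includeT2 = includeT2, seeds = seeds)
}

#' Run the full concordance pipeline
#'
#' Executes normalization, segmentation, analysis-volume construction,
#' hotspot extraction and pairwise concordance analysis for the three
#' pairs TBR_GE180-vs-rCE, TBR_FET-vs-rCE and TBR_GE180-vs-TBR_FET.
#' Deterministic given the configuration. A modality whose segmentation
#' is empty yields no hotspot and no overlap report for its pairs (the
#' remaining pairs are still produced); a pair whose voxel values are
#' degenerate yields no correlation report. All such events are logged.
#'
#' @param config a [RunConfig-class].
#' @return A [RunResult-class].
#' @export
runPipeline <- function(config) {
    stopifnot(is(config, "RunConfig"))
    vols <- config@volumes
    msk <- config@masks
    sp <- vols$pet_tspo@spacing
    logLines <- character()
    note <- function(...) logLines <<- c(logLines, sprintf(...))

    bgTspo <- backgroundMean(vols$pet_tspo, msk$petBackground, "petBackground")
    bgAa <- backgroundMean(vols$pet_aa, msk$petBackground, "petBackground")
    bgNat <- backgroundMean(vols$t1_native, msk$mriBackground, "mriBackground")
    bgCe <- backgroundMean(vols$t1_ce, msk$mriBackground, "mriBackground")
    note("background means: pet_tspo %.6g, pet_aa %.6g, t1_native %.6g, t1_ce %.6g",
         bgTspo, bgAa, bgNat, bgCe)

    normalized <- list(
        TBR_GE180 = toTBR(vols$pet_tspo, bgTspo),
        TBR_FET = toTBR(vols$pet_aa, bgAa),
        rCE = suppressMessages(toRCE(vols$t1_ce, vols$t1_native, bgCe, bgNat)))
    if (config@includeT2)
        normalized$TBR_T2 <- toTBR(vols$t2,
                                   backgroundMean(vols$t2, msk$mriBackground,
                                                  "mriBackground"))
    nInv <- sum(normalized$rCE@invalid)
    if (nInv > 0L) note("rCE: %d voxel(s) excluded at the validity floor", nInv)

    confine <- if (!is.null(msk$confine)) msk$confine
        else maskVolume(!(msk$petBackground@membership |
                          msk$mriBackground@membership), sp)

    segTags <- names(normalized)
    segmentations <- stats::setNames(vector("list", length(segTags)), segTags)
    for (tag in segTags) {
        thr <- unname(config@thresholds[tag])
        seeds <- config@seeds[[tag]]
        if (is.null(seeds))
            seeds <- autoSeeds(normalized[[tag]], thr, confine,
                               config@connectivity)
        if (nrow(seeds) == 0L) {
            note("%s: no supra-threshold seed at threshold %.3g; empty segmentation",
                 tag, thr)
            segmentations[[tag]] <- new("SegmentationResult",
                mask = maskVolume(array(FALSE, gridDim(confine)), sp),
                threshold = thr, seeds = seeds,
                connectivity = config@connectivity, modality = tag)
        } else {
            segmentations[[tag]] <- suppressWarnings(
                growIsocontour(normalized[[tag]], thr, seeds, confine,
                               config@connectivity, modality = tag))
        }
        note("%s: threshold %.3g, %d seed(s), %d voxel(s) segmented",
             tag, thr, nrow(seeds),
             sum(segmentations[[tag]]@mask@membership))
    }

    analysisMask <- analysisVolume(segmentations)
    note("analysis volume: %d voxel(s)", sum(analysisMask@membership))
    if (!any(analysisMask@membership))
        stop("analysis volume is empty: no modality segmented any voxel")

    nHot <- hotspotSize(config@hotspotDiameterMm, sp)
    hotTags <- c("TBR_GE180", "TBR_FET", "rCE")
    hotspots <- stats::setNames(vector("list", length(hotTags)), hotTags)
    for (tag in hotTags) {
        region <- segmentations[[tag]]@mask
        if (!any(region@membership)) {
            note("%s: empty segmentation, no hotspot", tag)
            next
        }
        hotspots[[tag]] <- suppressWarnings(
            extractHotspot(normalized[[tag]], region, nHot,
                           config@connectivity,
                           diameterMm = config@hotspotDiameterMm,
                           modality = tag))
        note("%s: hotspot of %d voxel(s)", tag,
             sum(hotspots[[tag]]@mask@membership))
    }

    # correlations over the analysis volume, excluding rCE-invalid voxels
    sel <- analysisMask@membership & !normalized$rCE@invalid
    correlations <- quadrants <- overlaps <-
        stats::setNames(vector("list", length(.PAIRS)), names(.PAIRS))
    for (pn in names(.PAIRS)) {
        p <- .PAIRS[[pn]]
        correlations[[pn]] <- tryCatch(
            voxelwiseCorrelation(normalized[[p["x"]]]@values[sel],
                                 normalized[[p["y"]]]@values[sel],
                                 xLabel = p["x"], yLabel = p["y"]),
            error = function(e) {
                note("%s: correlation skipped (%s)", pn, conditionMessage(e))
                NULL
            })
        quadrants[[pn]] <- quadrantClassify(
            segmentations[[p["y"]]]@mask, segmentations[[p["x"]]]@mask,
            analysisMask, firstLabel = p["y"], secondLabel = p["x"])
        h1 <- hotspots[[p["y"]]]; h2 <- hotspots[[p["x"]]]
        if (is.null(h1) || is.null(h2)) {
            note("%s: overlap report skipped (missing hotspot)", pn)
        } else {
            overlaps[[pn]] <- overlapReport(h1@mask, h2@mask, sp,
                                            v1Label = p["y"], v2Label = p["x"])
        }
    }

    new("RunResult", normalized = normalized, segmentations = segmentations,
        analysisMask = analysisMask, hotspots = hotspots,
        correlations = correlations, quadrants = quadrants,
        overlaps = overlaps, log = logLines)
}

.reportList <- function(result) {
    list(
        correlations = lapply(result@correlations, function(cr) {
            if (is.null(cr)) return(NULL)
            list(ordinate = cr@yLabel, abscissa = cr@xLabel, r = cr@r,
                 slope = cr@slope, intercept = cr@intercept,
                 p_value = cr@pValue, n_voxels = cr@nVoxels,
                 strength = cr@strength, significance = cr@significance,
                 note = cr@note)
        }),
        quadrants = lapply(result@quadrants, function(q) {
            if (is.null(q)) return(NULL)
            list(first = q@firstLabel, second = q@secondLabel,
                 counts = as.list(q@counts),
                 fractions = as.list(q@fractions), n_total = q@nTotal)
        }),
        overlaps = lapply(result@overlaps, function(o) {
            if (is.null(o)) return(NULL)
            list(v1 = o@v1Label, v2 = o@v2Label, dice = o@dice,
                 ahd_mm = o@ahdMm,
                 directed_ahd_mm = as.list(o@directedAhdMm),
                 frac_v1_only = o@fracV1Only, frac_v2_only = o@fracV2Only,
                 frac_intersection = o@fracIntersection,
                 n_v1 = o@nV1, n_v2 = o@nV2, n_union = o@nUnion)
        }),
        log = result@log)
}

#' Write all reports and derived volumes of a run
#'
#' Emits a JSON report bundle, a CSV overlap summary (sub-volume
#' percentages of the united volume, Dice and AHD per pair), the
#' normalized images, segmentation and hotspot masks as NIfTI-1 volumes,
#' and the run log. Output is byte-stable across reruns of the same
#' configuration.
#'
#' @param result a [RunResult-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeReports <- function(result, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.reportList(result),
                         file.path(dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    ov <- result@overlaps
    keep <- !vapply(ov, is.null, TRUE)
    df <- do.call(rbind, lapply(ov[keep], function(o) {
        data.frame(pair = paste(o@v1Label, "vs", o@v2Label),
                   v1_only_pct = 100 * o@fracV1Only,
                   v2_only_pct = 100 * o@fracV2Only,
                   intersection_pct = 100 * o@fracIntersection,
                   dice = o@dice, ahd_mm = o@ahdMm)
    }))
    if (!is.null(df))
        utils::write.csv(df, file.path(dir, "overlap_summary.csv"),
                         row.names = FALSE)
    for (tag in names(result@normalized))
        writeVolume(result@normalized[[tag]],
                    file.path(dir, paste0(tolower(tag), ".nii.gz")))
    for (tag in names(result@segmentations))
        writeMask(result@segmentations[[tag]]@mask,
                  file.path(dir, paste0("seg_", tolower(tag), ".nii.gz")))
    for (tag in names(result@hotspots))
        if (!is.null(result@hotspots[[tag]]))
            writeMask(result@hotspots[[tag]]@mask,
                      file.path(dir, paste0("hotspot_", tolower(tag), ".nii.gz")))
    writeLines(result@log, file.path(dir, "run_log.txt"))
    invisible(dir)
}
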