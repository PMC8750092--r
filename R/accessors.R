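# Constructors, accessors and show() methods for the core containers.

#' Create a VoxelGrid
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @return A [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(array(1, c(8, 8, 8)), c(2.036, 2.036, 2.027))
#' gridDim(g)
#' @export
voxelGrid <- function(values, spacingMm) {
    storage.mode(values) <- "double"
    new("VoxelGrid", values = values, spacing = as.numeric(spacingMm))
}

#' Create a MaskVolume
#'
#' @param membership 3D logical (or coercible 0/1) array.
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @return A [MaskVolume-class].
#' @export
maskVolume <- function(membership, spacingMm) {
    m <- array(as.logical(membership), dim(membership))
    new("MaskVolume", membership = m, spacing = as.numeric(spacingMm))
}

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelValues", "VoxelGrid", function(x) x@values)

#' @rdname VoxelGrid-class
#' @export
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname MaskVolume-class
#' @export
setMethod("voxelSpacing", "MaskVolume", function(x) x@spacing)

#' @rdname VoxelGrid-class
#' @export
setMethod("gridDim", "VoxelGrid", function(x) dim(x@values))

#' @rdname MaskVolume-class
#' @export
setMethod("gridDim", "MaskVolume", function(x) dim(x@membership))

#' @rdname MaskVolume-class
#' @export
setMethod("membership", "MaskVolume", function(x) x@membership)

#' @rdname MaskVolume-class
#' @export
setMethod("voxelCount", "MaskVolume", function(x) sum(x@membership))

#' @rdname NormalizedImage-class
#' @export
setMethod("normKind", "NormalizedImage", function(x) x@kind)

#' @rdname NormalizedImage-class
#' @export
setMethod("backgroundValue", "NormalizedImage", function(x) x@background)

#' @rdname NormalizedImage-class
#' @export
setMethod("invalidVoxels", "NormalizedImage", function(x) x@invalid)

#' @rdname SegmentationResult-class
#' @export
setMethod("segmentationMask", "SegmentationResult", function(x) x@mask)

#' @rdname HotspotVolume-class
#' @export
setMethod("segmentationMask", "HotspotVolume", function(x) x@mask)

setMethod("show", "VoxelGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("%s: %s voxels @ (%s) mm, range [%.4g, %.4g]\n",
        class(object), paste(d, collapse = " x "),
        paste(format(object@spacing, digits = 5), collapse = ", "),
        min(object@values), max(object@values)))
})

setMethod("show", "NormalizedImage", function(object) {
    d <- dim(object@values)
    cat(sprintf("NormalizedImage (%s): %s voxels @ (%s) mm\n",
        object@kind, paste(d, collapse = " x "),
        paste(format(object@spacing, digits = 5), collapse = ", ")))
    cat(sprintf("  background: %s; invalid voxels: %d\n",
        paste(format(object@background, digits = 5), collapse = ", "),
        sum(object@invalid)))
})

setMethod("show", "MaskVolume", function(object) {
    cat(sprintf("MaskVolume: %d of %s voxels set @ (%s) mm\n",
        sum(object@membership),
        paste(dim(object@membership), collapse = " x "),
        paste(format(object@spacing, digits = 5), collapse = ", ")))
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf(
        "SegmentationResult [%s]: threshold %.3g, %d seeds, %s connectivity, %d voxels\n",
        object@modality, object@threshold, nrow(object@seeds),
        object@connectivity, sum(object@mask@membership)))
})

setMethod("show", "HotspotVolume", function(object) {
    cat(sprintf(
        "HotspotVolume [%s]: %d voxels (target %d), seed (%s)%s\n",
        object@modality, sum(object@mask@membership), object@nVoxels,
        paste(object@seed, collapse = ", "),
        if (is.finite(object@diameterMm))
            sprintf(", equivalent sphere %.3g mm", object@diameterMm)
        else ""))
})

setMethod("show", "ConcordanceReport", function(object) {
    cat(sprintf("ConcordanceReport: %s (ordinate) vs %s (abscissa)\n",
        object@yLabel, object@xLabel))
    cat(sprintf("  r = %.4f (%s, %s), slope = %.4f, intercept = %.4f, n = %d\n",
        object@r, object@strength, object@significance,
        object@slope, object@intercept, object@nVoxels))
    for (nt in object@note) cat("  note:", nt, "\n")
})

setMethod("show", "QuadrantSummary", function(object) {
    cat(sprintf("QuadrantSummary: %s vs %s over %d voxels\n",
        object@firstLabel, object@secondLabel, object@nTotal))
    print(round(object@fractions, 4))
})

setMethod("show", "OverlapReport", function(object) {
    cat(sprintf("OverlapReport: %s vs %s\n", object@v1Label, object@v2Label))
    cat(sprintf("  Dice = %.4f, AHD = %.3f mm (directed %.3f / %.3f)\n",
        object@dice, object@ahdMm,
        object@directedAhdMm[1L], object@directedAhdMm[2L]))
    cat(sprintf("  fractions of union: V1-only %.3f, V2-only %.3f, intersection %.3f\n",
        object@fracV1Only, object@fracV2Only, object@fracIntersection))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec: %s voxels @ (%s) mm, %d lesion(s), rho = %.2f, enhancement %.2f, seed %d\n",
        paste(object@gridShape, collapse = " x "),
        paste(format(object@spacingMm, digits = 5), collapse = ", "),
        length(object@lesions), object@rhoTarget,
        object@enhancementFactor, object@seed))
})

setMethod("show", "RunResult", function(object) {
    cat("RunResult\n")
    cat("  normalized:", paste(names(object@normalized), collapse = ", "), "\n")
    cat("  analysis volume:", sum(object@analysisMask@membership), "voxels\n")
    cat("  pairs:", paste(names(object@correlations), collapse = ", "), "\n")
})
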