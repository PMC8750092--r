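# Iso-contour region-growing segmentation inside a confining mask, and
# construction of the union analysis volume.

.MODALITY_THRESHOLDS <- c(TBR_FET = 1.6, TBR_GE180 = 1.8,
                          rCE = 1.3, TBR_T2 = 1.3)

#' Default iso-contour segmentation threshold per modality
#'
#' 1.6 for TBR_FET (the biopsy-validated biological-tumor-volume
#' threshold on amino-acid PET), 1.8 for TBR_GE180 (reflecting the lower
#' healthy-background signal of the TSPO tracer), and 1.3 for rCE and
#' TBR_T2 (visually defined hyperintensity thresholds).
#'
#' @param modality one of "TBR_FET", "TBR_GE180", "rCE", "TBR_T2".
#' @return The threshold as a single number.
#' @examples
#' defaultThreshold("TBR_FET")   # 1.6
#' @export
defaultThreshold <- function(modality) {
    if (length(modality) != 1L || !modality %in% names(.MODALITY_THRESHOLDS))
        stop("unknown modality tag; valid tags: ",
             paste(names(.MODALITY_THRESHOLDS), collapse = ", "))
    unname(.MODALITY_THRESHOLDS[modality])
}

# eligibility: inside confine, at or above threshold, and (for rCE-type
# images) not flagged invalid -- invalid voxels count as sub-threshold
.eligibleVoxels <- function(image, threshold, confine) {
    elig <- confine@membership & (image@values >= threshold)
    if (is(image, "NormalizedImage")) elig <- elig & !image@invalid
    elig
}

#' Seeded iso-contour region growing
#'
#' Grows, from user-defined (or [autoSeeds()]-derived) seed points, all
#' connected voxels inside the confining mask whose intensity is at or
#' above the iso-contour threshold. The result is the union over seeds of
#' the connected supra-threshold component containing each seed; seeds
#' below the threshold contribute nothing.
#'
#' @param image a [NormalizedImage-class] or plain [VoxelGrid-class].
#' @param threshold iso-contour threshold (inclusive).
#' @param seeds integer matrix of voxel indices (rows i,j,k), or a single
#'   index triple.
#' @param confine confining [MaskVolume-class]; all seeds must lie inside.
#' @param connectivity "face" (6-neighbour, default) or "full"
#'   (26-neighbour).
#' @param modality tag recorded in the result.
#' @return A [SegmentationResult-class]; an empty mask (with a warning)
#'   when no seed reaches the threshold.
#' @export
growIsocontour <- function(image, threshold, seeds, confine,
                           connectivity = c("face", "full"),
                           modality = NA_character_) {
    connectivity <- match.arg(connectivity)
    .checkSameGrid(image, confine, "image", "confining mask")
    seeds <- .asSeedMatrix(seeds)
    d <- dim(image@values)
    for (r in seq_len(nrow(seeds))) {
        s <- seeds[r, ]
        if (any(s < 1L) || any(s > d))
            stop(sprintf("seed (%s) lies outside the image grid",
                         paste(s, collapse = ", ")))
        if (!confine@membership[s[1L], s[2L], s[3L]])
            stop(sprintf("seed (%s) lies outside the confining mask",
                         paste(s, collapse = ", ")))
    }

    eligible <- .eligibleVoxels(image, threshold, confine)
    offsets <- .connOffsets(connectivity)
    visited <- array(FALSE, d)
    sl <- .linIndex(seeds, d)
    visited[sl[eligible[sl]]] <- TRUE
    if (any(visited)) {
        repeat {
            grown <- .growOnce(visited, eligible, offsets)
            if (sum(grown) == sum(visited)) break
            visited <- grown
        }
    }
    if (!any(visited))
        warning("region growing produced an empty mask (all seeds below threshold)")

    new("SegmentationResult",
        mask = maskVolume(visited, image@spacing),
        threshold = threshold, seeds = seeds,
        connectivity = connectivity, modality = modality)
}

#' Automatic seed points: supra-threshold strict local maxima
#'
#' Replaces user-defined seed points in unattended runs: returns every
#' voxel inside the confining mask that is at or above the threshold and
#' strictly greater than all of its neighbours (under the chosen
#' connectivity), in deterministic column-major scan order.
#'
#' @inheritParams growIsocontour
#' @return Integer matrix of voxel indices (possibly zero rows).
#' @export
autoSeeds <- function(image, threshold, confine,
                      connectivity = c("face", "full")) {
    connectivity <- match.arg(connectivity)
    .checkSameGrid(image, confine, "image", "confining mask")
    if (!any(confine@membership)) stop("confining mask is empty")
    v <- image@values
    offsets <- .connOffsets(connectivity)
    isMax <- array(TRUE, dim(v))
    for (r in seq_len(nrow(offsets)))
        isMax <- isMax & (v > .shift3d(v, offsets[r, ], -Inf))
    elig <- .eligibleVoxels(image, threshold, confine)
    idx <- which(isMax & elig, arr.ind = TRUE)
    dimnames(idx) <- NULL
    storage.mode(idx) <- "integer"
    idx
}

#' Union analysis volume
#'
#' Voxel-wise union of modality segmentations: all voxels with abnormal
#' signal in at least one modality, the volume over which voxel-wise
#' correlations are computed.
#'
#' @param masks nonempty list of [MaskVolume-class]s or
#'   [SegmentationResult-class]s on one grid.
#' @return The union [MaskVolume-class].
#' @export
analysisVolume <- function(masks) {
    if (!is.list(masks) || length(masks) == 0L)
        stop("'masks' must be a nonempty list")
    masks <- lapply(masks, function(m)
        if (is(m, "SegmentationResult")) m@mask else m)
    for (i in seq_along(masks)[-1L])
        .checkSameGrid(masks[[1L]], masks[[i]],
                       "mask 1", sprintf("mask %d", i))
    un <- Reduce(`|`, lapply(masks, membership))
    maskVolume(un, masks[[1L]]@spacing)
}
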