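# Hottest-N-voxel hotspot extraction by greedy region growing from the
# maximal-intensity voxel of a predefined volume.

#' Number of voxels in an equivalent sphere
#'
#' The hotspot voxel count N corresponding to a sphere of the given
#' diameter: round((pi/6) d^3 / (sx sy sz)) to the nearest integer, at
#' least 1. With a 10 mm diameter and near-isotropic 2 mm voxels
#' (2.036 x 2.036 x 2.027 mm) this gives the canonical 62 voxels.
#'
#' @param diameterMm sphere diameter in mm (> 0).
#' @param spacingMm numeric(3) voxel spacing in mm (> 0).
#' @return Integer voxel count.
#' @examples
#' hotspotSize(10, c(2.036, 2.036, 2.027))   # 62
#' @export
hotspotSize <- function(diameterMm, spacingMm) {
    if (!is.numeric(diameterMm) || length(diameterMm) != 1L ||
        diameterMm <= 0)
        stop("'diameterMm' must be a single positive number")
    if (length(spacingMm) != 3L || any(spacingMm <= 0))
        stop("'spacingMm' must be 3 positive voxel sizes")
    max(1L, as.integer(round(pi / 6 * diameterMm^3 / prod(spacingMm))))
}

#' Extract the hottest-N-voxel connected sub-volume
#'
#' Greedy region growing: start at the maximal-intensity voxel of the
#' predefined region, then repeatedly add the highest-valued region voxel
#' adjacent to the current mask until N voxels are collected. The result
#' is connected by construction and independent of manually placed
#' spherical VOIs. Ties (at seed selection or on the frontier) are broken
#' deterministically by lexicographic (column-major) voxel index.
#'
#' @param image the intensity [VoxelGrid-class] or
#'   [NormalizedImage-class].
#' @param region nonempty predefined [MaskVolume-class] (typically a
#'   modality's segmentation).
#' @param n target voxel count, e.g. from [hotspotSize()]; when n exceeds
#'   the region size the whole region is returned with a warning.
#' @param connectivity "face" (default) or "full".
#' @param diameterMm the equivalent-sphere diameter n was derived from
#'   (recorded only).
#' @param modality tag recorded in the result.
#' @return A [HotspotVolume-class].
#' @export
extractHotspot <- function(image, region, n,
                           connectivity = c("face", "full"),
                           diameterMm = NA_real_,
                           modality = NA_character_) {
    connectivity <- match.arg(connectivity)
    .checkSameGrid(image, region, "image", "region")
    if (!any(region@membership)) stop("predefined region is empty")
    if (!is.numeric(n) || length(n) != 1L || n < 1)
        stop("'n' must be a single integer >= 1")
    n <- as.integer(n)

    d <- dim(image@values)
    v <- as.vector(image@values)
    inRegion <- as.vector(region@membership)
    regionIdx <- which(inRegion)
    nTarget <- n
    if (n > length(regionIdx)) {
        warning(sprintf(
            "requested %d voxels but the region holds only %d; returning the whole region",
            n, length(regionIdx)))
        ord <- regionIdx[order(-v[regionIdx], regionIdx)]
        seed <- arrayInd(ord[1L], d)
        return(new("HotspotVolume",
            mask = maskVolume(region@membership, region@spacing),
            nVoxels = n, seed = as.integer(seed),
            diameterMm = diameterMm, modality = modality,
            growthOrder = as.integer(ord)))
    }

    offsets <- .connOffsets(connectivity)
    seedLin <- regionIdx[order(-v[regionIdx], regionIdx)][1L]
    inMask <- logical(length(v))
    inQueue <- logical(length(v))
    inMask[seedLin] <- TRUE
    growth <- integer(nTarget)
    growth[1L] <- seedLin
    cand <- .voxelNeighbours(seedLin, d, offsets)
    cand <- cand[inRegion[cand] & !inMask[cand]]
    inQueue[cand] <- TRUE

    k <- 1L
    while (k < nTarget) {
        if (length(cand) == 0L) {
            warning(sprintf(
                "hotspot growth exhausted its connected component after %d of %d voxels",
                k, nTarget))
            growth <- growth[seq_len(k)]
            break
        }
        best <- cand[order(-v[cand], cand)][1L]
        inMask[best] <- TRUE
        inQueue[best] <- FALSE
        cand <- cand[cand != best]
        k <- k + 1L
        growth[k] <- best
        nb <- .voxelNeighbours(best, d, offsets)
        nb <- nb[inRegion[nb] & !inMask[nb] & !inQueue[nb]]
        if (length(nb)) {
            inQueue[nb] <- TRUE
            cand <- c(cand, nb)
        }
    }

    new("HotspotVolume",
        mask = maskVolume(array(inMask, d), region@spacing),
        nVoxels = n, seed = as.integer(arrayInd(seedLin, d)),
        diameterMm = diameterMm, modality = modality,
        growthOrder = growth)
}
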