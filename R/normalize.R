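# Normalization of raw co-registered volumes into dimensionless analysis
# images: tumor-to-background ratio (TBR) for PET and relative contrast
# enhancement (rCE) for MRI.

# near-zero denominators (air, CSF) are excluded rather than propagated
.RCE_FLOOR_FACTOR <- 1e-6

#' Mean intensity within a background VOI
#'
#' Arithmetic, unweighted mean of the image over the member voxels of a
#' volume of interest — the background scalar used for TBR and rCE
#' normalization.
#'
#' @param image a [VoxelGrid-class] (or [NormalizedImage-class]).
#' @param voi a nonempty [MaskVolume-class] on the same grid.
#' @param voiName label used in error messages.
#' @return The mean intensity (a single positive number for physical
#'   images).
#' @export
backgroundMean <- function(image, voi, voiName = deparse(substitute(voi))) {
    .checkSameGrid(image, voi, "image", voiName)
    if (!any(voi@membership))
        stop(sprintf("background VOI '%s' is empty", voiName))
    mean(image@values[voi@membership])
}

#' Convert an image to a tumor-to-background ratio image
#'
#' Divides every voxel by the scalar background uptake, yielding a
#' dimensionless TBR image. Negative raw intensities (possible in noisy
#' reconstructions) are clipped to zero so ratio images stay nonnegative.
#'
#' @param image a [VoxelGrid-class].
#' @param bg positive background scalar, typically from
#'   [backgroundMean()].
#' @return A [NormalizedImage-class] tagged "TBR".
#' @export
toTBR <- function(image, bg) {
    if (!is.numeric(bg) || length(bg) != 1L || !is.finite(bg) || bg <= 0)
        stop("background 'bg' must be a single positive number")
    new("NormalizedImage",
        values = pmax(image@values / bg, 0), spacing = image@spacing,
        kind = "TBR", background = c(bg = bg),
        invalid = array(FALSE, dim(image@values)))
}

#' Compute a relative contrast enhancement (rCE) image
#'
#' rCE(v) = (ce(v) / bgCe) / (native(v) / bgNative): the
#' background-normalized post-contrast T1 divided voxel-wise by the
#' background-normalized pre-contrast T1, a surrogate for blood-brain
#' barrier leakage under the linear contrast-concentration assumption.
#' Voxels whose native intensity lies at or below a validity floor of
#' 1e-6 * bgNative are flagged invalid, set to zero, and excluded from
#' all downstream statistics.
#'
#' @param ce,native post- and pre-contrast T1 [VoxelGrid-class]s on the
#'   same grid.
#' @param bgCe,bgNative positive background scalars (white-matter VOI
#'   means).
#' @return A [NormalizedImage-class] tagged "rCE"; the count of excluded
#'   voxels is reported via a message when nonzero.
#' @export
toRCE <- function(ce, native, bgCe, bgNative) {
    .checkSameGrid(ce, native, "ce", "native")
    for (b in list(bgCe = bgCe, bgNative = bgNative))
        if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
            stop("background scalars must be single positive numbers")
    floorVal <- .RCE_FLOOR_FACTOR * bgNative
    invalid <- native@values <= floorVal
    vals <- array(0, dim(ce@values))
    ok <- !invalid
    vals[ok] <- (ce@values[ok] / bgCe) / (native@values[ok] / bgNative)
    vals <- pmax(vals, 0)
    nbad <- sum(invalid)
    if (nbad > 0L)
        message(sprintf(
            "toRCE: %d voxel(s) with native T1 at or below the validity floor excluded",
            nbad))
    new("NormalizedImage",
        values = vals, spacing = ce@spacing,
        kind = "rCE", background = c(bgCe = bgCe, bgNative = bgNative),
        invalid = invalid)
}
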