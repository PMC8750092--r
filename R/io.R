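# NIfTI-1 I/O for volumes and masks (via RNifti).

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a .nii / .nii.gz file holding a 3D scalar volume.
#' @return A [VoxelGrid-class] with the spacing taken from the header.
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
        arr <- arr[, , , 1L]
    if (length(dim(arr)) != 3L)
        stop(sprintf("'%s' is not a 3D volume (dims: %s)", path,
                     paste(dim(arr), collapse = "x")))
    voxelGrid(arr, abs(RNifti::pixdim(img)[1:3]))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param grid a [VoxelGrid-class].
#' @param path output path (.nii or .nii.gz).
#' @return Invisibly, the path.
#' @export
writeVolume <- function(grid, path) {
    stopifnot(is(grid, "VoxelGrid"))
    img <- RNifti::asNifti(grid@values)
    RNifti::pixdim(img) <- grid@spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Any nonzero voxel is taken as a member.
#'
#' @inheritParams readVolume
#' @return A [MaskVolume-class].
#' @export
readMask <- function(path) {
    g <- readVolume(path)
    maskVolume(g@values != 0, g@spacing)
}

#' Write a binary mask as a 0/1 NIfTI-1 volume
#'
#' @param mask a [MaskVolume-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "MaskVolume"))
    writeVolume(voxelGrid(array(as.double(mask@membership), dim(mask@membership)),
                          mask@spacing), path)
}

#' Write a phantom (volumes plus truth manifest) to a directory
#'
#' Each modality becomes a NIfTI-1 volume; the ground truth (centres,
#' offsets, programmed correlation, seed) is serialized as a JSON
#' manifest and the truth masks as 0/1 volumes.
#'
#' @param phantom the list returned by [generatePhantom()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writePhantom <- function(phantom, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(phantom$volumes))
        writeVolume(phantom$volumes[[m]], file.path(dir, paste0(m, ".nii.gz")))
    tr <- phantom$truth
    for (m in names(tr@lesionMasks))
        writeMask(tr@lesionMasks[[m]],
                  file.path(dir, paste0("truth_mask_", m, ".nii.gz")))
    writeMask(tr@petBackground, file.path(dir, "pet_background.nii.gz"))
    writeMask(tr@mriBackground, file.path(dir, "mri_background.nii.gz"))
    manifest <- list(
        centers = lapply(tr@centers, function(m) unname(apply(m, 1L, c,
                                                              simplify = FALSE))),
        offsets = tr@offsets,
        rhoTarget = tr@rhoTarget,
        seed = tr@seed)
    jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
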