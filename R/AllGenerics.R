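#' @rdname VoxelGrid-class
#' @param object,x an object of the respective class
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname MaskVolume-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname MaskVolume-class
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname NormalizedImage-class
#' @export
setGeneric("normKind", function(x) standardGeneric("normKind"))

#' @rdname NormalizedImage-class
#' @export
setGeneric("backgroundValue", function(x) standardGeneric("backgroundValue"))

#' @rdname NormalizedImage-class
#' @export
setGeneric("invalidVoxels", function(x) standardGeneric("invalidVoxels"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("segmentationMask", function(x) standardGeneric("segmentationMask"))
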