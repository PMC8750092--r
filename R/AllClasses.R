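#' @import methods
NULL

#' VoxelGrid: a 3D scalar image with physical voxel spacing
#'
#' The elementary container of the package: a dense 3D array of finite
#' scalar intensities together with the physical voxel spacing in mm.
#' All volumes entering a joint analysis must live on the identical grid
#' (same shape, same spacing); the package refuses to resample.
#'
#' @slot values 3D numeric array of voxel intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm, all positive.
#' @export
setClass("VoxelGrid",
    representation(values = "array", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("'values' must be a 3D array")
    if (!is.numeric(v)) return("'values' must be numeric")
    if (any(!is.finite(v))) return("'values' must be finite everywhere")
    s <- object@spacing
    if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
        return("'spacing' must be 3 positive voxel sizes in mm")
    TRUE
})

#' MaskVolume: a binary volume on a voxel grid
#'
#' Membership volume delimiting VOIs, segmentations and hotspots, carrying
#' the same spacing bookkeeping as [VoxelGrid-class].
#'
#' @slot membership 3D logical array.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @export
setClass("MaskVolume",
    representation(membership = "array", spacing = "numeric"))

setValidity("MaskVolume", function(object) {
    m <- object@membership
    if (length(dim(m)) != 3L) return("'membership' must be a 3D array")
    if (!is.logical(m)) return("'membership' must be logical")
    if (anyNA(m)) return("'membership' must not contain NA")
    s <- object@spacing
    if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
        return("'spacing' must be 3 positive voxel sizes in mm")
    TRUE
})

#' NormalizedImage: a dimensionless TBR or rCE volume
#'
#' A [VoxelGrid-class] whose intensities are ratios: tumor-to-background
#' ratio (TBR, voxel intensity over the mean of a healthy contralesional
#' background VOI) or relative contrast enhancement (rCE, the ratio of the
#' background-normalized post- and pre-contrast T1 images). Voxels whose
#' rCE denominator fell at or below the validity floor are recorded in
#' \code{invalid} and are excluded from all downstream statistics.
#'
#' @slot kind "TBR" or "rCE".
#' @slot background named numeric, the background scalar(s) used.
#' @slot invalid 3D logical array flagging excluded voxels.
#' @export
setClass("NormalizedImage",
    contains = "VoxelGrid",
    representation(kind = "character", background = "numeric",
                   invalid = "array"))

setValidity("NormalizedImage", function(object) {
    if (!object@kind %in% c("TBR", "rCE"))
        return("'kind' must be \"TBR\" or \"rCE\"")
    if (any(object@background <= 0) || any(!is.finite(object@background)))
        return("'background' scalars must be strictly positive")
    if (any(object@values < 0)) return("normalized values must be nonnegative")
    if (!identical(dim(object@invalid), dim(object@values)))
        return("'invalid' must match the value array dimensions")
    if (!is.logical(object@invalid)) return("'invalid' must be logical")
    TRUE
})

#' SegmentationResult: an iso-contour region-growing segmentation
#'
#' @slot mask the segmented [MaskVolume-class].
#' @slot threshold iso-contour threshold (inclusive, value >= threshold).
#' @slot seeds integer matrix of seed voxel indices (rows of i,j,k).
#' @slot connectivity "face" (6-neighbour) or "full" (26-neighbour).
#' @slot modality source modality tag, e.g. "TBR_FET".
#' @export
setClass("SegmentationResult",
    representation(mask = "MaskVolume", threshold = "numeric",
                   seeds = "matrix", connectivity = "character",
                   modality = "character"))

setValidity("SegmentationResult", function(object) {
    if (!object@connectivity %in% c("face", "full"))
        return("'connectivity' must be \"face\" or \"full\"")
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        return("'threshold' must be a single finite number")
    TRUE
})

#' HotspotVolume: the connected hottest-N-voxel sub-volume
#'
#' @slot mask the hotspot [MaskVolume-class].
#' @slot nVoxels requested voxel count N.
#' @slot seed integer(3), the maximal-intensity voxel the growth started at.
#' @slot diameterMm equivalent-sphere diameter N was derived from (NA when
#'   N was given directly).
#' @slot modality source modality tag.
#' @slot growthOrder linear voxel indices in the order they were added;
#'   allows replaying the greedy growth for auditing.
#' @export
setClass("HotspotVolume",
    representation(mask = "MaskVolume", nVoxels = "integer",
                   seed = "integer", diameterMm = "numeric",
                   modality = "character", growthOrder = "integer"))

#' ConcordanceReport: voxel-wise Pearson correlation with regression
#'
#' @slot r Pearson product-moment correlation coefficient.
#' @slot slope,intercept ordinary least-squares fit of ordinate on abscissa.
#' @slot pValue two-sided p from the t statistic with n - 2 df.
#' @slot nVoxels number of voxels entering the correlation.
#' @slot strength categorical strength class derived from |r|.
#' @slot significance "***", "**", "*" or "n.s.".
#' @slot xLabel,yLabel modality on the abscissa / ordinate.
#' @slot note caveats attached to the report.
#' @export
setClass("ConcordanceReport",
    representation(r = "numeric", slope = "numeric", intercept = "numeric",
                   pValue = "numeric", nVoxels = "integer",
                   strength = "character", significance = "character",
                   xLabel = "character", yLabel = "character",
                   note = "character"))

setValidity("ConcordanceReport", function(object) {
    if (abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
    if (object@nVoxels < 3L) return("'nVoxels' must be >= 3")
    if (!object@strength %in%
        c("none/very-weak", "weak", "moderate", "strong"))
        return("unknown strength class")
    TRUE
})

#' QuadrantSummary: four-class voxel membership within the analysis volume
#'
#' Every analysis-volume voxel is assigned to exactly one class by its
#' membership in two modality segmentations: contained in both, in the
#' first only, in the second only, or in neither.
#'
#' @slot counts named integer(4): bothPositive, firstOnly, secondOnly,
#'   bothNegative.
#' @slot fractions the counts divided by the analysis-volume size.
#' @slot nTotal analysis-volume voxel count.
#' @slot firstLabel,secondLabel the two modality tags.
#' @export
setClass("QuadrantSummary",
    representation(counts = "integer", fractions = "numeric",
                   nTotal = "integer", firstLabel = "character",
                   secondLabel = "character"))

setValidity("QuadrantSummary", function(object) {
    nm <- c("bothPositive", "firstOnly", "secondOnly", "bothNegative")
    if (!identical(names(object@counts), nm))
        return("counts must be named bothPositive/firstOnly/secondOnly/bothNegative")
    if (sum(object@counts) != object@nTotal)
        return("counts must partition the analysis volume exactly")
    if (abs(sum(object@fractions) - 1) > 1e-9)
        return("fractions must sum to 1 within 1e-9")
    TRUE
})

#' OverlapReport: Dice, average Hausdorff distance and sub-volume fractions
#'
#' Summarises spatial concordance of a volume pair: the Dice coefficient
#' D = 2|V1 n V2| / (|V1| + |V2|), the directed and symmetric average
#' Hausdorff distances in mm, and the fractions of the united volume held
#' exclusively by each volume and by their intersection.
#'
#' @slot dice Dice coefficient in [0, 1].
#' @slot ahdMm symmetric average Hausdorff distance (max of the directed).
#' @slot directedAhdMm named numeric(2), dAHD(V1,V2) and dAHD(V2,V1).
#' @slot fracV1Only,fracV2Only,fracIntersection fractions of |V1 u V2|.
#' @slot nV1,nV2,nUnion voxel counts.
#' @slot v1Label,v2Label modality tags.
#' @export
setClass("OverlapReport",
    representation(dice = "numeric", ahdMm = "numeric",
                   directedAhdMm = "numeric",
                   fracV1Only = "numeric", fracV2Only = "numeric",
                   fracIntersection = "numeric",
                   nV1 = "integer", nV2 = "integer", nUnion = "integer",
                   v1Label = "character", v2Label = "character"))

setValidity("OverlapReport", function(object) {
    if (object@dice < -1e-12 || object@dice > 1 + 1e-12)
        return("Dice must lie in [0, 1]")
    fr <- object@fracV1Only + object@fracV2Only + object@fracIntersection
    if (abs(fr - 1) > 1e-9) return("overlap fractions must sum to 1")
    if (length(object@ahdMm) == 1L && is.finite(object@ahdMm) &&
        length(object@directedAhdMm) == 2L &&
        all(is.finite(object@directedAhdMm)) &&
        abs(object@ahdMm - max(object@directedAhdMm)) > 1e-9)
        return("symmetric AHD must be the max of the directed AHDs")
    TRUE
})

#' LesionSpec: one synthetic lesion with per-modality centres
#'
#' Describes a single lesion of the phantom. Each modality (and the
#' contrast-enhancement field, key "ce") may place its centre at a
#' different physical position, which programs a known inter-modality
#' hotspot offset.
#'
#' @slot centers named list of numeric(3) centres in mm; keys among
#'   "pet_tspo", "pet_aa", "t1_native", "t2", "ce".
#' @slot radiiMm numeric(3) lesion semi-axes in mm.
#' @slot amplitude named numeric, peak intensity excess over background per
#'   modality.
#' @slot profile "gaussian" (smooth fall-off, sigma = radius / 2) or
#'   "flat" (constant inside the ellipsoid).
#' @export
setClass("LesionSpec",
    representation(centers = "list", radiiMm = "numeric",
                   amplitude = "numeric", profile = "character"))

setValidity("LesionSpec", function(object) {
    if (!object@profile %in% c("gaussian", "flat"))
        return("profile must be \"gaussian\" or \"flat\"")
    if (length(object@radiiMm) != 3L || any(object@radiiMm <= 0))
        return("'radiiMm' must be 3 positive semi-axes")
    if (all(object@amplitude <= 0))
        return("amplitude must be positive for at least one modality")
    ok <- names(object@centers) %in%
        c("pet_tspo", "pet_aa", "t1_native", "t2", "ce")
    if (!all(ok)) return("unknown modality key in 'centers'")
    if (!all(vapply(object@centers, length, 1L) == 3L))
        return("each centre must be a numeric triple (mm)")
    TRUE
})

#' PhantomSpec: full description of a synthetic multi-modal phantom
#'
#' @slot gridShape integer(3) voxels per axis, all >= 8.
#' @slot spacingMm numeric(3) voxel spacing in mm.
#' @slot backgroundLevel named numeric, healthy-background intensity per
#'   modality (pet_tspo, pet_aa, t1_native, t2).
#' @slot noiseSd named numeric, additive Gaussian noise sd per modality.
#' @slot lesions list of [LesionSpec-class].
#' @slot rhoTarget programmed voxel-wise correlation between the two PET
#'   lesion texture fields, in [-1, 1].
#' @slot enhancementFactor nonnegative scale of the contrast-enhancement
#'   field multiplying the native T1.
#' @slot textureCV coefficient of variation of the correlated lesion
#'   texture relative to the lesion amplitude.
#' @slot seed integer RNG seed; identical specs generate bit-identical
#'   volumes.
#' @export
setClass("PhantomSpec",
    representation(gridShape = "integer", spacingMm = "numeric",
                   backgroundLevel = "numeric", noiseSd = "numeric",
                   lesions = "list", rhoTarget = "numeric",
                   enhancementFactor = "numeric", textureCV = "numeric",
                   seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
        return("'gridShape' must be 3 integers, all >= 8")
    if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
        return("'spacingMm' must be 3 positive voxel sizes")
    if (abs(object@rhoTarget) > 1) return("|rhoTarget| must be <= 1")
    if (any(object@noiseSd < 0)) return("'noiseSd' must be nonnegative")
    if (object@enhancementFactor < 0)
        return("'enhancementFactor' must be nonnegative")
    if (any(object@backgroundLevel <= 0))
        return("'backgroundLevel' must be positive")
    if (!all(vapply(object@lesions, is, TRUE, "LesionSpec")))
        return("'lesions' must be a list of LesionSpec objects")
    TRUE
})

#' PhantomTruth: generator ground truth accompanying a phantom
#'
#' @slot centers named list; per modality a (lesions x 3) matrix of centre
#'   coordinates in mm.
#' @slot offsets data.frame of pairwise Euclidean centre offsets in mm per
#'   lesion (columns lesion, first, second, offsetMm).
#' @slot rhoTarget programmed PET-pair voxel-wise correlation.
#' @slot lesionMasks named list of true lesion [MaskVolume-class]s.
#' @slot petBackground,mriBackground lesion-free background VOIs (the
#'   crescent analogue for PET and the white-matter analogue for MRI).
#' @slot seed the RNG seed used.
#' @export
setClass("PhantomTruth",
    representation(centers = "list", offsets = "data.frame",
                   rhoTarget = "numeric", lesionMasks = "list",
                   petBackground = "MaskVolume",
                   mriBackground = "MaskVolume", seed = "integer"))

#' RunConfig: a fully resolved pipeline run configuration
#'
#' @slot volumes named list of [VoxelGrid-class]s: pet_tspo, pet_aa,
#'   t1_native, t1_ce and optionally t2.
#' @slot masks named list: petBackground, mriBackground and optionally
#'   confine [MaskVolume-class]s.
#' @slot thresholds named numeric segmentation thresholds per modality tag.
#' @slot hotspotDiameterMm equivalent-sphere diameter for the hotspot size.
#' @slot connectivity "face" or "full".
#' @slot includeT2 whether TBR_T2 joins the analysis-volume union.
#' @slot seeds named list of explicit seed matrices per modality tag
#'   (empty entries fall back to automatic local-maximum seeds).
#' @export
setClass("RunConfig",
    representation(volumes = "list", masks = "list", thresholds = "numeric",
                   hotspotDiameterMm = "numeric", connectivity = "character",
                   includeT2 = "logical", seeds = "list"))

#' RunResult: all products of one pipeline run
#'
#' @slot normalized named list of [NormalizedImage-class]s.
#' @slot segmentations named list of [SegmentationResult-class]s.
#' @slot analysisMask union analysis [MaskVolume-class].
#' @slot hotspots named list of [HotspotVolume-class]s (NULL entries where
#'   a segmentation was empty).
#' @slot correlations named list of [ConcordanceReport-class]s per pair.
#' @slot quadrants named list of [QuadrantSummary-class]s per pair.
#' @slot overlaps named list of [OverlapReport-class]s per hotspot pair.
#' @slot log character vector of run messages (thresholds, seed and voxel
#'   counts, exclusions).
#' @export
setClass("RunResult",
    representation(normalized = "list", segmentations = "list",
                   analysisMask = "MaskVolume", hotspots = "list",
                   correlations = "list", quadrants = "list",
                   overlaps = "list", log = "character"))
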