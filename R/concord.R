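# Pairwise concordance statistics: voxel-wise Pearson correlation with
# regression slope and strength/significance classes, quadrant
# classification, Dice coefficient, directed and symmetric average
# Hausdorff distance, and sub-volume fractions.

.AUTOCORR_NOTE <- paste(
    "p-value treats voxels as independent observations;",
    "spatial autocorrelation is ignored")

#' Voxel-wise Pearson correlation with regression
#'
#' Product-moment correlation of two paired voxel-value sequences, the
#' ordinary least-squares slope and intercept of y on x, and a two-sided
#' p-value from the t statistic with n - 2 degrees of freedom. The
#' strength class follows the cut points |r| <= 0.3 none/very weak,
#' <= 0.5 weak, <= 0.7 moderate, > 0.7 strong (boundary values fall to
#' the lower class).
#'
#' @param x,y equal-length numeric vectors (>= 3 values, non-constant).
#' @param xLabel,yLabel modality on the abscissa / ordinate, recorded in
#'   the report.
#' @return A [ConcordanceReport-class].
#' @examples
#' voxelwiseCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))   # r = s = 0.6
#' @export
voxelwiseCorrelation <- function(x, y, xLabel = "x", yLabel = "y") {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    if (length(x) < 3L)
        stop("at least 3 paired voxel values are required")
    if (stats::sd(x) == 0)
        stop(sprintf("'%s' is constant; correlation undefined", xLabel))
    if (stats::sd(y) == 0)
        stop(sprintf("'%s' is constant; correlation undefined", yLabel))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
    r <- unname(ct$estimate)
    cf <- stats::coef(stats::lm(y ~ x))
    new("ConcordanceReport",
        r = r, slope = unname(cf[2L]), intercept = unname(cf[1L]),
        pValue = ct$p.value, nVoxels = length(x),
        strength = strengthClass(r),
        significance = significanceClass(ct$p.value),
        xLabel = xLabel, yLabel = yLabel,
        note = .AUTOCORR_NOTE)
}

#' Correlation strength class
#'
#' @param r Pearson coefficient, |r| <= 1.
#' @return "none/very-weak", "weak", "moderate" or "strong".
#' @export
strengthClass <- function(r) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) > 1)
        stop("'r' must be a single number with |r| <= 1")
    a <- abs(r)
    if (a <= 0.3) "none/very-weak"
    else if (a <= 0.5) "weak"
    else if (a <= 0.7) "moderate"
    else "strong"
}

#' Significance class from a p-value
#'
#' @param p p-value in [0, 1].
#' @return "***" (p < 0.001), "**" (p < 0.01), "*" (p < 0.05) or "n.s.".
#' @export
significanceClass <- function(p) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        stop("'p' must be a single value in [0, 1]")
    if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "n.s."
}

#' Quadrant classification of analysis-volume voxels
#'
#' Assigns every voxel of the analysis volume to exactly one of four
#' classes by its membership in two modality segmentations: contained in
#' both, in the first only, in the second only, or in neither (the
#' red / orange / green / blue coding of concordance scatter plots).
#' Membership is intersected with the analysis volume.
#'
#' @param first,second modality [MaskVolume-class]s (or
#'   [SegmentationResult-class]s).
#' @param analysis nonempty analysis [MaskVolume-class].
#' @param firstLabel,secondLabel modality tags for the report.
#' @return A [QuadrantSummary-class].
#' @export
quadrantClassify <- function(first, second, analysis,
                             firstLabel = "first", secondLabel = "second") {
    if (is(first, "SegmentationResult")) first <- first@mask
    if (is(second, "SegmentationResult")) second <- second@mask
    .checkSameGrid(first, analysis, firstLabel, "analysis volume")
    .checkSameGrid(second, analysis, secondLabel, "analysis volume")
    if (!any(analysis@membership)) stop("analysis volume is empty")
    a <- analysis@membership
    f <- first@membership & a
    s <- second@membership & a
    counts <- c(bothPositive = sum(f & s),
                firstOnly = sum(f & !s),
                secondOnly = sum(!f & s),
                bothNegative = sum(a & !f & !s))
    nTot <- sum(a)
    new("QuadrantSummary",
        counts = stats::setNames(as.integer(counts), names(counts)),
        fractions = counts / nTot, nTotal = nTot,
        firstLabel = firstLabel, secondLabel = secondLabel)
}

#' Dice similarity coefficient
#'
#' D = 2 |V1 n V2| / (|V1| + |V2|), in [0, 1].
#'
#' @param v1,v2 [MaskVolume-class]s on one grid, not both empty.
#' @return The Dice coefficient.
#' @export
diceCoefficient <- function(v1, v2) {
    .checkSameGrid(v1, v2, "V1", "V2")
    n1 <- sum(v1@membership); n2 <- sum(v2@membership)
    if (n1 + n2 == 0L)
        stop("Dice coefficient is undefined for two empty volumes")
    2 * sum(v1@membership & v2@membership) / (n1 + n2)
}

# mm coordinates of mask member voxel centres
.maskCoordsMm <- function(mask, spacingMm) {
    idx <- which(mask@membership, arr.ind = TRUE)
    .voxelCoordsMm(idx, spacingMm)
}

#' Directed average Hausdorff distance
#'
#' dAHD(V1, V2): the mean, over all voxel centres a of V1, of the
#' distance to the closest voxel centre b of V2, in mm. Distances use
#' voxel centres; sub-voxel surface geometry is not modelled.
#'
#' @param v1,v2 nonempty [MaskVolume-class]s.
#' @param spacingMm voxel spacing in mm (defaults to v1's).
#' @return The directed average Hausdorff distance in mm.
#' @export
directedAHD <- function(v1, v2, spacingMm = voxelSpacing(v1)) {
    .checkSameGrid(v1, v2, "V1", "V2")
    if (!any(v1@membership)) stop("V1 is empty; dAHD undefined")
    if (!any(v2@membership)) stop("V2 is empty; no closest point exists")
    A <- .maskCoordsMm(v1, spacingMm)
    B <- .maskCoordsMm(v2, spacingMm)
    # direct squared differences: no cancellation, exact to double precision
    total <- 0
    for (i in seq_len(nrow(A))) {
        dx <- B[, 1L] - A[i, 1L]
        dy <- B[, 2L] - A[i, 2L]
        dz <- B[, 3L] - A[i, 3L]
        total <- total + sqrt(min(dx * dx + dy * dy + dz * dz))
    }
    total / nrow(A)
}

#' Symmetric average Hausdorff distance
#'
#' AHD(V1, V2) = max(dAHD(V1, V2), dAHD(V2, V1)), the outlier-robust
#' symmetric variant of the Hausdorff distance, in mm.
#'
#' @inheritParams directedAHD
#' @return The symmetric average Hausdorff distance in mm.
#' @export
averageHausdorff <- function(v1, v2, spacingMm = voxelSpacing(v1)) {
    max(directedAHD(v1, v2, spacingMm), directedAHD(v2, v1, spacingMm))
}

#' Sub-volume fractions of the united volume
#'
#' |V1 \\ V2|, |V2 \\ V1| and |V1 n V2|, each as a fraction of
#' |V1 u V2|.
#'
#' @param v1,v2 [MaskVolume-class]s with a nonempty union.
#' @return Named numeric(3): v1Only, v2Only, intersection (summing to 1).
#' @export
overlapFractions <- function(v1, v2) {
    .checkSameGrid(v1, v2, "V1", "V2")
    m1 <- v1@membership; m2 <- v2@membership
    nU <- sum(m1 | m2)
    if (nU == 0L) stop("union of V1 and V2 is empty")
    c(v1Only = sum(m1 & !m2), v2Only = sum(m2 & !m1),
      intersection = sum(m1 & m2)) / nU
}

#' Full overlap report for a volume pair
#'
#' Bundles [diceCoefficient()], the directed and symmetric
#' [averageHausdorff()] distances and [overlapFractions()] into one
#' [OverlapReport-class].
#'
#' @inheritParams directedAHD
#' @param v1Label,v2Label modality tags.
#' @return An [OverlapReport-class].
#' @export
overlapReport <- function(v1, v2, spacingMm = voxelSpacing(v1),
                          v1Label = "V1", v2Label = "V2") {
    if (is(v1, "HotspotVolume")) v1 <- v1@mask
    if (is(v2, "HotspotVolume")) v2 <- v2@mask
    d12 <- directedAHD(v1, v2, spacingMm)
    d21 <- directedAHD(v2, v1, spacingMm)
    fr <- overlapFractions(v1, v2)
    new("OverlapReport",
        dice = diceCoefficient(v1, v2),
        ahdMm = max(d12, d21),
        directedAhdMm = c(dAHD12 = d12, dAHD21 = d21),
        fracV1Only = unname(fr["v1Only"]),
        fracV2Only = unname(fr["v2Only"]),
        fracIntersection = unname(fr["intersection"]),
        nV1 = sum(v1@membership), nV2 = sum(v2@membership),
        nUnion = sum(v1@membership | v2@membership),
        v1Label = v1Label, v2Label = v2Label)
}
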