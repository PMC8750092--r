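# Synthetic multi-modal phantom generator.
#
# Emulates the statistical structure the concordance analysis assumes:
# co-registered volumes with a noisy homogeneous background, one or more
# lesions whose per-modality intensity fields carry a programmable
# voxel-wise correlation, per-modality lesion centres with programmable
# spatial offsets, and a post-contrast T1 equal to the pre-contrast T1
# scaled by a lesion-localised enhancement field. Scanner physics
# (partial volume, attenuation, motion, registration error) is out of
# scope by design.

.PHANTOM_MODALITIES <- c("pet_tspo", "pet_aa", "t1_native", "t2")
.INTENSITY_FLOOR <- 1e-6   # all emitted intensities are clipped below this

#' Describe one synthetic lesion
#'
#' @param center numeric(3) lesion centre in mm, used for every modality
#'   not overridden in \code{centerByModality}.
#' @param radiiMm numeric(3) ellipsoid semi-axes in mm (scalar recycled).
#' @param amplitude named numeric, peak excess over background per
#'   modality; modalities absent from the vector get amplitude 0.
#' @param profile "gaussian" (sigma = radius / 2, smooth monotone
#'   fall-off with a unique peak) or "flat" (constant inside the
#'   ellipsoid; useful when the lesion interior must have no
#'   deterministic intensity gradient).
#' @param centerByModality named list of numeric(3) overrides; keys among
#'   "pet_tspo", "pet_aa", "t1_native", "t2" and "ce" (the centre of the
#'   contrast-enhancement field).
#' @return A [LesionSpec-class].
#' @examples
#' les <- lesionSpec(center = c(40, 40, 40), radiiMm = 12,
#'                   amplitude = c(pet_tspo = 2, pet_aa = 2, t2 = 60))
#' @export
lesionSpec <- function(center, radiiMm = 10,
                       amplitude = c(pet_tspo = 2, pet_aa = 2,
                                     t1_native = 0, t2 = 60),
                       profile = c("gaussian", "flat"),
                       centerByModality = list()) {
    profile <- match.arg(profile)
    if (length(radiiMm) == 1L) radiiMm <- rep(radiiMm, 3L)
    amp <- structure(rep(0, length(.PHANTOM_MODALITIES)),
                     names = .PHANTOM_MODALITIES)
    amp[names(amplitude)] <- amplitude
    centers <- stats::setNames(
        rep(list(as.numeric(center)), length(.PHANTOM_MODALITIES) + 1L),
        c(.PHANTOM_MODALITIES, "ce"))
    for (nm in names(centerByModality))
        centers[[nm]] <- as.numeric(centerByModality[[nm]])
    new("LesionSpec", centers = centers, radiiMm = as.numeric(radiiMm),
        amplitude = amp, profile = profile)
}

#' Describe a synthetic multi-modal phantom
#'
#' Defaults follow the geometry of a clinical co-registered PET/MRI stack
#' (near-isotropic 2 mm voxels) with PET backgrounds of 1 (so that TBR
#' equals raw intensity in the noise-free limit) and arbitrary MRI units
#' of 100. Noise is additive homoscedastic Gaussian, by default 5% of the
#' background level per modality.
#'
#' @param gridShape integer(3), voxels per axis (all >= 8).
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @param backgroundLevel named numeric per modality.
#' @param noiseSd named numeric per modality (t1_ce reuses t1_native's).
#' @param lesions list of [LesionSpec-class].
#' @param rhoTarget programmed voxel-wise correlation of the two PET
#'   lesion texture fields, in [-1, 1].
#' @param enhancementFactor scale e of the enhancement field: the
#'   post-contrast T1 is the native T1 times (1 + e * E) with E in [0, 1].
#' @param textureCV coefficient of variation of the correlated lesion
#'   texture relative to the lesion amplitude.
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 48L),
                        spacingMm = c(2.036, 2.036, 2.027),
                        backgroundLevel = c(pet_tspo = 1, pet_aa = 1,
                                            t1_native = 100, t2 = 100),
                        noiseSd = 0.05 * backgroundLevel,
                        lesions = list(),
                        rhoTarget = 0.8,
                        enhancementFactor = 1,
                        textureCV = 0.25,
                        seed = 1L) {
    bg <- structure(rep(NA_real_, 4L), names = .PHANTOM_MODALITIES)
    bg[names(backgroundLevel)] <- backgroundLevel
    ns <- structure(rep(0, 4L), names = .PHANTOM_MODALITIES)
    ns[names(noiseSd)] <- noiseSd
    if (anyNA(bg))
        stop("backgroundLevel must name all of: ",
             paste(.PHANTOM_MODALITIES, collapse = ", "))
    spec <- new("PhantomSpec",
        gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
        backgroundLevel = bg, noiseSd = ns,
        lesions = lesions, rhoTarget = as.numeric(rhoTarget),
        enhancementFactor = as.numeric(enhancementFactor),
        textureCV = as.numeric(textureCV), seed = as.integer(seed))
    .checkLesionFit(spec)
    spec
}

# lesions must fit inside the grid with a >= 2-voxel margin, for every
# per-modality centre that carries signal (and always for "ce")
.checkLesionFit <- function(spec) {
    lo <- 2 * spec@spacingMm
    hi <- (spec@gridShape - 3L) * spec@spacingMm
    for (i in seq_along(spec@lesions)) {
        les <- spec@lesions[[i]]
        for (nm in names(les@centers)) {
            if (nm != "ce" && les@amplitude[nm] <= 0) next
            ctr <- les@centers[[nm]]
            if (any(ctr - les@radiiMm < lo) || any(ctr + les@radiiMm > hi))
                stop(sprintf(
                    "lesion %d (%s centre at %s mm, radii %s mm) does not fit inside the %s grid with a 2-voxel margin",
                    i, nm, paste(format(ctr), collapse = ", "),
                    paste(format(les@radiiMm), collapse = ", "),
                    paste(spec@gridShape, collapse = "x")))
        }
    }
    invisible(TRUE)
}

#' Build a pair of correlated modulation fields
#'
#' Given a shared standardized field S and a target correlation rho,
#' returns F1 = S and F2 = rho * S + sqrt(1 - rho^2) * E where E is an
#' independent standard-normal field drawn from the current RNG stream.
#' When S itself is i.i.d. standard normal, the expected voxel-wise
#' Pearson correlation of F1 and F2 equals rho.
#'
#' @param shared 3D numeric array or [VoxelGrid-class], the shared field S.
#' @param rho target correlation in [-1, 1].
#' @return list(first = F1, second = F2) of arrays with dim(S).
#' @examples
#' set.seed(7)
#' f <- correlatedFields(array(rnorm(1000), c(10, 10, 10)), 0.8)
#' cor(as.vector(f$first), as.vector(f$second))
#' @export
correlatedFields <- function(shared, rho) {
    if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1)
        stop("'rho' must be a single number with |rho| <= 1")
    s <- if (is(shared, "VoxelGrid")) shared@values else shared
    e <- array(stats::rnorm(length(s)), dim(s))
    list(first = s, second = rho * s + sqrt(1 - rho^2) * e)
}

# squared normalized ellipsoid distance field for a centre/radii pair;
# coordinates are voxel centres at (index - 1) * spacing
.ellipsoidR2 <- function(gridShape, spacingMm, center, radiiMm) {
    u <- lapply(1:3, function(ax) {
        x <- (seq_len(gridShape[ax]) - 1) * spacingMm[ax]
        ((x - center[ax]) / radiiMm[ax])^2
    })
    outer(outer(u[[1L]], u[[2L]], "+"), u[[3L]], "+")
}

# profile in [0, 1]: gaussian with sigma = radius/2, or flat indicator
.lesionProfile <- function(r2, profile) {
    if (profile == "gaussian") exp(-2 * r2) else as.numeric(r2 <= 1)
}

#' Generate a synthetic co-registered multi-modal phantom
#'
#' Emits five volumes on the identical grid — two PET-like tracers
#' ("pet_tspo", "pet_aa"), pre- and post-contrast T1 ("t1_native",
#' "t1_ce") and T2 ("t2") — together with the generator ground truth.
#' Inside each lesion the two PET fields are modulated by a pair of
#' [correlatedFields()] with the programmed correlation; the
#' post-contrast T1 equals the native T1 multiplied voxel-wise by
#' (1 + enhancementFactor * E) with E a lesion-localised field in [0, 1],
#' before independent per-modality noise is added. Identical specs
#' (including seed) produce bit-identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{volumes} (named list of five
#'   [VoxelGrid-class]s) and \code{truth} (a [PhantomTruth-class]).
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    .checkLesionFit(spec)
    d <- spec@gridShape
    sp <- spec@spacingMm
    n <- prod(d)

    set.seed(spec@seed)
    shared <- array(stats::rnorm(n), d)
    flds <- correlatedFields(shared, spec@rhoTarget)
    texture <- list(pet_tspo = flds$first, pet_aa = flds$second,
                    t1_native = NULL, t2 = NULL)

    clean <- lapply(spec@backgroundLevel, function(bg) array(bg, d))
    enhance <- array(0, d)          # E field, max over lesions, in [0, 1]
    r2ByMod <- lapply(stats::setNames(nm = c(.PHANTOM_MODALITIES, "ce")),
                      function(nm) vector("list", length(spec@lesions)))

    for (i in seq_along(spec@lesions)) {
        les <- spec@lesions[[i]]
        for (m in .PHANTOM_MODALITIES) {
            r2 <- .ellipsoidR2(d, sp, les@centers[[m]], les@radiiMm)
            r2ByMod[[m]][[i]] <- r2
            if (les@amplitude[m] <= 0) next
            prof <- .lesionProfile(r2, les@profile)
            contrib <- les@amplitude[m] * prof
            if (!is.null(texture[[m]]))
                contrib <- contrib * (1 + spec@textureCV * texture[[m]])
            clean[[m]] <- clean[[m]] + contrib
        }
        r2ce <- .ellipsoidR2(d, sp, les@centers[["ce"]], les@radiiMm)
        r2ByMod[["ce"]][[i]] <- r2ce
        enhance <- pmax(enhance, .lesionProfile(r2ce, les@profile))
    }

    clean$t1_ce <- clean$t1_native * (1 + spec@enhancementFactor * enhance)

    noiseSd <- c(spec@noiseSd, t1_ce = unname(spec@noiseSd["t1_native"]))
    emitOrder <- c("pet_tspo", "pet_aa", "t1_native", "t1_ce", "t2")
    volumes <- stats::setNames(vector("list", 5L), emitOrder)
    for (m in emitOrder) {
        img <- clean[[m]]
        if (noiseSd[m] > 0)
            img <- img + array(stats::rnorm(n, 0, noiseSd[m]), d)
        volumes[[m]] <- voxelGrid(pmax(img, .INTENSITY_FLOOR), sp)
    }

    truth <- .phantomTruth(spec, r2ByMod)
    list(volumes = volumes, truth = truth)
}

.phantomTruth <- function(spec, r2ByMod) {
    d <- spec@gridShape
    sp <- spec@spacingMm
    nles <- length(spec@lesions)

    centers <- lapply(stats::setNames(nm = c(.PHANTOM_MODALITIES, "ce")),
        function(m) {
            ctr <- t(vapply(spec@lesions,
                            function(l) l@centers[[m]], numeric(3L)))
            if (nles == 0L) ctr <- matrix(numeric(0), 0L, 3L)
            ctr
        })

    pairs <- list(c("pet_tspo", "pet_aa"), c("pet_tspo", "ce"),
                  c("pet_aa", "ce"))
    offs <- do.call(rbind, lapply(seq_len(nles), function(i) {
        do.call(rbind, lapply(pairs, function(p) {
            data.frame(lesion = i, first = p[1L], second = p[2L],
                offsetMm = sqrt(sum((centers[[p[1L]]][i, ] -
                                     centers[[p[2L]]][i, ])^2)))
        }))
    }))
    if (is.null(offs))
        offs <- data.frame(lesion = integer(), first = character(),
                           second = character(), offsetMm = numeric())

    lesionMasks <- lapply(
        stats::setNames(nm = c("pet_tspo", "pet_aa", "ce", "t2")),
        function(m) {
            inside <- array(FALSE, d)
            for (i in seq_len(nles)) {
                if (m != "ce" && spec@lesions[[i]]@amplitude[m] <= 0) next
                inside <- inside | (r2ByMod[[m]][[i]] <= 1)
            }
            maskVolume(inside, sp)
        })

    # lesion-free exclusion zone: any lesion ellipsoid inflated by 1.5
    nearLesion <- array(FALSE, d)
    for (m in names(r2ByMod)) for (r2 in r2ByMod[[m]])
        if (!is.null(r2)) nearLesion <- nearLesion | (r2 <= 1.5^2)

    slab <- max(2L, d[1L] %/% 8L)
    xIdx <- slice.index(nearLesion, 1L)
    petBg <- (xIdx <= slab) & !nearLesion
    wmBg <- (xIdx > d[1L] - slab) & !nearLesion
    if (!any(petBg) || !any(wmBg))
        stop("no lesion-free background region; enlarge the grid or move lesions")

    new("PhantomTruth",
        centers = centers, offsets = offs, rhoTarget = spec@rhoTarget,
        lesionMasks = lesionMasks,
        petBackground = maskVolume(petBg, sp),
        mriBackground = maskVolume(wmBg, sp),
        seed = spec@seed)
}
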