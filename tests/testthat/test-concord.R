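# Pairwise concordance statistics: correlation, classes, quadrants,
# Dice, average Hausdorff distances and sub-volume fractions.

test_that("voxelwiseCorrelation recovers exact and hand-computed fits", {
    x <- c(0.5, 1.4, 2.2, 3.9, 4.1)
    idr <- voxelwiseCorrelation(x, x)
    expect_equal(idr@r, 1)
    expect_equal(idr@slope, 1)
    expect_equal(idr@intercept, 0, tolerance = 1e-12)

    ln <- voxelwiseCorrelation(x, -2 * x + 5)
    expect_equal(ln@r, -1)
    expect_equal(ln@slope, -2)
    expect_equal(ln@intercept, 5)

    # product-moment formula by hand: Sxy = 3, Sxx = Syy = 5
    hand <- voxelwiseCorrelation(c(1, 2, 3, 4), c(2, 1, 4, 3))
    expect_equal(hand@r, 0.6)
    expect_equal(hand@slope, 0.6)
    expect_equal(hand@nVoxels, 4L)

    expect_error(voxelwiseCorrelation(rep(2, 5), 1:5, xLabel = "TBR_FET"),
                 "TBR_FET.*constant")
    expect_error(voxelwiseCorrelation(1:2, 1:2), "3")
    expect_error(voxelwiseCorrelation(1:4, 1:5), "equal length")
})

test_that("correlation is invariant under positive affine rescaling", {
    set.seed(151)
    x <- rnorm(200); y <- 0.8 * x + rnorm(200, 0, 0.4)
    base <- voxelwiseCorrelation(x, y)
    resc <- voxelwiseCorrelation(2.5 * x + 1, 0.3 * y - 4)
    expect_equal(resc@r, base@r, tolerance = 1e-12)
    expect_equal(resc@slope, (0.3 / 2.5) * base@slope, tolerance = 1e-12)
    expect_equal(resc@pValue, base@pValue, tolerance = 1e-9)
})

test_that("strength and significance classes follow the cut points", {
    expect_identical(strengthClass(-0.8), "strong")
    expect_identical(strengthClass(0.4), "weak")
    expect_identical(strengthClass(0), "none/very-weak")
    expect_identical(strengthClass(0.55), "moderate")
    # boundary values fall to the lower class
    expect_identical(strengthClass(0.3), "none/very-weak")
    expect_identical(strengthClass(-0.5), "weak")
    expect_identical(strengthClass(0.7), "moderate")
    expect_error(strengthClass(1.2), "r")

    expect_identical(significanceClass(1e-5), "***")
    expect_identical(significanceClass(0.005), "**")
    expect_identical(significanceClass(0.03), "*")
    expect_identical(significanceClass(0.2), "n.s.")
})

test_that("quadrant classification partitions the analysis volume", {
    set.seed(161)
    d <- c(8L, 8L, 8L)
    sp <- c(1, 1, 1)
    ana <- fullMask(d, sp)
    m <- randomMask(d, 100, sp)
    same <- quadrantClassify(m, m, ana)
    expect_equal(unname(same@counts["firstOnly"]), 0L)
    expect_equal(unname(same@counts["secondOnly"]), 0L)
    expect_equal(unname(same@counts["bothPositive"]), voxelCount(m))

    a <- array(FALSE, d); a[1:200] <- TRUE
    b <- array(FALSE, d); b[201:512] <- TRUE
    disj <- quadrantClassify(maskVolume(a, sp), maskVolume(b, sp), ana)
    expect_equal(unname(disj@counts["bothPositive"]), 0L)
    expect_equal(unname(disj@counts["bothNegative"]), 0L)
    expect_equal(unname(disj@counts["firstOnly"]), 200L)

    # truth-table oracle on random masks
    for (i in 1:5) {
        f <- randomMask(d, 120, sp); s <- randomMask(d, 120, sp)
        an <- randomMask(d, 300, sp)
        if (voxelCount(an) == 0L) next
        q <- quadrantClassify(f, s, an)
        want <- c(bothPositive = 0L, firstOnly = 0L, secondOnly = 0L,
                  bothNegative = 0L)
        for (lin in which(membership(an))) {
            fin <- membership(f)[lin]; sin <- membership(s)[lin]
            cls <- if (fin && sin) "bothPositive" else if (fin) "firstOnly"
                   else if (sin) "secondOnly" else "bothNegative"
            want[cls] <- want[cls] + 1L
        }
        expect_identical(q@counts, want)
        expect_equal(sum(q@fractions), 1, tolerance = 1e-9)
        # bothPositive is symmetric under swapping the masks
        q2 <- quadrantClassify(s, f, an)
        expect_identical(q@counts[["bothPositive"]],
                         q2@counts[["bothPositive"]])
    }
    expect_error(quadrantClassify(m, m, maskVolume(array(FALSE, d), sp)),
                 "empty")
})

test_that("Dice coefficient follows the set formula", {
    d <- c(6L, 6L, 6L)
    sp <- c(1, 1, 1)
    m <- randomMask(d, 40, sp)
    expect_equal(diceCoefficient(m, m), 1)

    a <- array(FALSE, d); a[1:4] <- TRUE
    b <- array(FALSE, d); b[10:13] <- TRUE
    expect_equal(diceCoefficient(maskVolume(a, sp), maskVolume(b, sp)), 0)

    a2 <- array(FALSE, d); a2[1:4] <- TRUE
    b2 <- array(FALSE, d); b2[3:6] <- TRUE
    expect_equal(diceCoefficient(maskVolume(a2, sp), maskVolume(b2, sp)), 0.5)
    expect_error(diceCoefficient(maskVolume(array(FALSE, d), sp),
                                 maskVolume(array(FALSE, d), sp)),
                 "empty")
})

test_that("directed and symmetric AHD match trivial geometry", {
    d <- c(10L, 10L, 10L)
    sp <- c(1, 1, 1)
    sub <- array(FALSE, d); sub[2:3, 2, 2] <- TRUE
    sup <- array(FALSE, d); sup[2:5, 2, 2] <- TRUE
    expect_equal(directedAHD(maskVolume(sub, sp), maskVolume(sup, sp)), 0)

    a <- array(FALSE, d); a[2, 2, 2] <- TRUE
    b <- array(FALSE, d); b[5, 2, 2] <- TRUE
    expect_equal(directedAHD(maskVolume(a, sp), maskVolume(b, sp)), 3)
    expect_equal(averageHausdorff(maskVolume(a, sp), maskVolume(b, sp)), 3)

    # anisotropic spacing enters the metric
    spA <- c(2, 1, 1)
    expect_equal(directedAHD(maskVolume(a, spA), maskVolume(b, spA)), 6)

    expect_error(directedAHD(maskVolume(a, sp),
                             maskVolume(array(FALSE, d), sp)),
                 "closest point")
})

test_that("AHD agrees with the all-pairs oracle and is symmetric", {
    set.seed(171)
    d <- c(10L, 10L, 10L)
    sp <- c(2.036, 2.036, 2.027)
    for (i in 1:20) {
        v1 <- randomMask(d, 50, sp)
        v2 <- randomMask(d, 50, sp)
        if (voxelCount(v1) == 0L || voxelCount(v2) == 0L) next
        expect_equal(directedAHD(v1, v2),
                     oracleDirectedAHD(membership(v1), membership(v2), sp),
                     tolerance = 1e-9)
        expect_equal(averageHausdorff(v1, v2), averageHausdorff(v2, v1),
                     tolerance = 1e-12)
    }
})

test_that("overlap fractions partition the united volume", {
    d <- c(8L, 8L, 8L)
    sp <- c(1, 1, 1)
    m <- randomMask(d, 30, sp)
    expect_equal(overlapFractions(m, m),
                 c(v1Only = 0, v2Only = 0, intersection = 1))

    a <- array(FALSE, d); a[1:10] <- TRUE
    b <- array(FALSE, d); b[11:20] <- TRUE
    expect_equal(overlapFractions(maskVolume(a, sp), maskVolume(b, sp)),
                 c(v1Only = 0.5, v2Only = 0.5, intersection = 0))

    # |V1| = |V2| = 62 with an 8-voxel intersection
    a2 <- array(FALSE, d); a2[1:62] <- TRUE
    b2 <- array(FALSE, d); b2[55:116] <- TRUE
    expect_equal(overlapFractions(maskVolume(a2, sp), maskVolume(b2, sp)),
                 c(v1Only = 54, v2Only = 54, intersection = 8) / 116)
    expect_error(overlapFractions(maskVolume(array(FALSE, d), sp),
                                  maskVolume(array(FALSE, d), sp)),
                 "empty")
})

test_that("equal-size volumes satisfy the Dice-fraction identity", {
    set.seed(181)
    d <- c(9L, 9L, 9L)
    sp <- c(1, 1, 1)
    for (i in 1:10) {
        n <- 40L
        m1 <- array(FALSE, d); m1[sample.int(prod(d), n)] <- TRUE
        m2 <- array(FALSE, d); m2[sample.int(prod(d), n)] <- TRUE
        v1 <- maskVolume(m1, sp); v2 <- maskVolume(m2, sp)
        rep <- overlapReport(v1, v2)
        expect_equal(rep@fracV1Only, rep@fracV2Only)
        u <- rep@fracIntersection
        expect_equal(rep@dice, 2 * u / (1 + u), tolerance = 1e-12)
        # zero AHD iff identical for equal-size volumes
        expect_identical(rep@ahdMm == 0, identical(m1, m2))
    }
})
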