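# Iso-contour region growing, default thresholds, analysis volume and
# automatic seeding.

test_that("supra-threshold constant image fills the seed's confine component", {
    d <- c(8L, 8L, 8L)
    sp <- c(1, 1, 1)
    img <- voxelGrid(array(2, d), sp)
    conf <- array(FALSE, d)
    conf[2:4, 2:4, 2:4] <- TRUE   # one connected confine region
    conf[6:7, 6:7, 6:7] <- TRUE   # a second, disconnected one
    seg <- growIsocontour(img, 1.6, c(3L, 3L, 3L), maskVolume(conf, sp))
    expect_equal(sum(membership(segmentationMask(seg))), 27)
    expect_true(all(membership(segmentationMask(seg))[2:4, 2:4, 2:4]))
})

test_that("a sub-threshold seed yields an empty mask with a warning", {
    d <- c(6L, 6L, 6L)
    img <- voxelGrid(array(1, d), c(1, 1, 1))
    expect_warning(
        seg <- growIsocontour(img, 1.6, c(3L, 3L, 3L), fullMask(d)),
        "empty")
    expect_equal(sum(membership(segmentationMask(seg))), 0)
})

test_that("growth from one blob does not leak into a disconnected blob", {
    d <- c(12L, 12L, 12L)
    sp <- c(1, 1, 1)
    v <- array(1, d)
    v[2:4, 2:4, 2:4] <- 2      # blob 1
    v[8:10, 8:10, 8:10] <- 2   # blob 2, separated by sub-threshold voxels
    img <- voxelGrid(v, sp)
    seg <- growIsocontour(img, 1.6, c(3L, 3L, 3L), fullMask(d, sp))
    got <- membership(segmentationMask(seg))
    want <- oracleGrow(v, 1.6, matrix(c(3L, 3L, 3L), 1), array(TRUE, d),
                       "face")
    expect_identical(got, want)
    expect_equal(sum(got), 27)
    expect_false(any(got[8:10, 8:10, 8:10]))
})

test_that("region growing matches the brute-force oracle on random images", {
    set.seed(71)
    d <- c(12L, 12L, 12L)
    for (i in 1:10) {
        img <- randomStructuredImage(d)
        conf <- array(runif(prod(d)) < 0.9, d)
        for (conn in c("face", "full")) {
            sIdx <- which(conf)
            seeds <- arrayInd(sample(sIdx, 3L), d)
            storage.mode(seeds) <- "integer"
            seg <- suppressWarnings(growIsocontour(
                img, 0.8, seeds, maskVolume(conf, c(1, 1, 1)), conn))
            want <- oracleGrow(voxelValues(img), 0.8, seeds, conf, conn)
            expect_identical(membership(segmentationMask(seg)), want)
        }
    }
})

test_that("raising the threshold never enlarges the mask", {
    set.seed(81)
    d <- c(14L, 14L, 14L)
    img <- randomStructuredImage(d)
    conf <- fullMask(d)
    seed <- arrayInd(which.max(voxelValues(img)), d)
    storage.mode(seed) <- "integer"
    prev <- NULL
    for (thr in c(0.3, 0.6, 0.9, 1.2)) {
        m <- membership(segmentationMask(suppressWarnings(
            growIsocontour(img, thr, seed, conf))))
        if (!is.null(prev))
            expect_true(all(!m | prev))   # m subset of prev
        prev <- m
    }
})

test_that("the mask is independent of seed order", {
    set.seed(91)
    d <- c(12L, 12L, 12L)
    img <- randomStructuredImage(d)
    seeds <- arrayInd(sample(prod(d), 5L), d)
    storage.mode(seeds) <- "integer"
    a <- suppressWarnings(growIsocontour(img, 0.7, seeds, fullMask(d)))
    b <- suppressWarnings(growIsocontour(img, 0.7, seeds[5:1, ], fullMask(d)))
    expect_identical(membership(segmentationMask(a)),
                     membership(segmentationMask(b)))
})

test_that("seeds outside the confining mask are rejected by name", {
    d <- c(6L, 6L, 6L)
    img <- voxelGrid(array(2, d), c(1, 1, 1))
    conf <- array(FALSE, d); conf[2:3, 2:3, 2:3] <- TRUE
    expect_error(growIsocontour(img, 1, c(5L, 5L, 5L),
                                maskVolume(conf, c(1, 1, 1))),
                 "\\(5, 5, 5\\).*confining mask")
    expect_error(growIsocontour(img, 1, c(9L, 2L, 2L),
                                maskVolume(conf, c(1, 1, 1))),
                 "\\(9, 2, 2\\)")
})

test_that("default thresholds match the modality conventions", {
    expect_equal(defaultThreshold("TBR_FET"), 1.6)
    expect_equal(defaultThreshold("TBR_GE180"), 1.8)
    expect_equal(defaultThreshold("rCE"), 1.3)
    expect_equal(defaultThreshold("TBR_T2"), 1.3)
    expect_error(defaultThreshold("SUV"), "TBR_FET")
})

test_that("analysisVolume is the voxel-wise union", {
    set.seed(99)
    d <- c(8L, 8L, 8L)
    m1 <- randomMask(d, 40)
    expect_identical(membership(analysisVolume(list(m1, m1))),
                     membership(m1))

    a <- array(FALSE, d); a[1:10] <- TRUE
    b <- array(FALSE, d); b[101:110] <- TRUE
    un <- analysisVolume(list(maskVolume(a, c(1, 1, 1)),
                              maskVolume(b, c(1, 1, 1))))
    expect_equal(sum(membership(un)), 20)

    ms <- list(randomMask(d, 60), randomMask(d, 60), randomMask(d, 60))
    want <- membership(ms[[1]]) | membership(ms[[2]]) | membership(ms[[3]])
    expect_identical(membership(analysisVolume(ms)), want)

    expect_error(analysisVolume(list()), "nonempty")
})

test_that("autoSeeds finds exactly the supra-threshold strict local maxima", {
    ph <- generatePhantom(smallPhantomSpec(seed = 17L, noise = FALSE,
                                           textureCV = 0))
    img <- toTBR(ph$volumes$pet_tspo,
                 backgroundMean(ph$volumes$pet_tspo, ph$truth@petBackground))
    d <- gridDim(img)
    seeds <- autoSeeds(img, 1.8, fullMask(d, voxelSpacing(img)))
    expect_equal(nrow(seeds), 1L)
    expect_equal(as.vector(seeds[1, ]),
                 as.vector(arrayInd(which.max(voxelValues(img)), d)))

    # everything below threshold -> no seeds
    expect_equal(nrow(autoSeeds(img, 100, fullMask(d, voxelSpacing(img)))), 0L)

    # two separated peaks -> two seeds
    spec2 <- phantomSpec(
        gridShape = c(48L, 48L, 48L),
        lesions = list(
            lesionSpec(center = c(28, 48, 48), radiiMm = 10),
            lesionSpec(center = c(66, 48, 48), radiiMm = 10)),
        noiseSd = c(pet_tspo = 0, pet_aa = 0, t1_native = 0, t2 = 0),
        textureCV = 0, seed = 2L)
    ph2 <- generatePhantom(spec2)
    img2 <- toTBR(ph2$volumes$pet_tspo,
                  backgroundMean(ph2$volumes$pet_tspo,
                                 ph2$truth@petBackground))
    seeds2 <- autoSeeds(img2, 1.8, fullMask(d, voxelSpacing(img2)))
    expect_equal(nrow(seeds2), 2L)
})

test_that("rCE-invalid voxels behave as sub-threshold in region growing", {
    d <- c(6L, 6L, 6L)
    sp <- c(1, 1, 1)
    native <- array(100, d)
    native[3, 3, 3] <- 0      # floor voxel in the middle of a bright block
    ce <- array(200, d)
    rce <- suppressMessages(toRCE(voxelGrid(ce, sp), voxelGrid(native, sp),
                                  100, 100))
    seg <- growIsocontour(rce, 1.3, c(2L, 2L, 2L), fullMask(d, sp))
    m <- membership(segmentationMask(seg))
    expect_false(m[3, 3, 3])
    expect_equal(sum(m), prod(d) - 1L)
})
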