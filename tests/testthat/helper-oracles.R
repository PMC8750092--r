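# Independent brute-force oracles. These deliberately avoid the package's
# internal machinery (array-shift flood fill, frontier queues, cross-product
# distance formulas) so that agreement is meaningful.

oracleOffsets <- function(connectivity) {
    if (connectivity == "face") {
        rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
              c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
    } else {
        g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
        g[rowSums(abs(g)) > 0, , drop = FALSE]
    }
}

# connected-component labelling by explicit per-voxel stack flood
oracleLabelComponents <- function(eligible, connectivity) {
    d <- dim(eligible)
    offs <- oracleOffsets(connectivity)
    allIJK <- arrayInd(seq_len(prod(d)), d)
    labels <- array(0L, d)
    cur <- 0L
    for (start in which(eligible)) {
        if (labels[start] != 0L) next
        cur <- cur + 1L
        stack <- start
        labels[start] <- cur
        while (length(stack) > 0L) {
            p <- stack[length(stack)]
            stack <- stack[-length(stack)]
            q <- sweep(offs, 2L, allIJK[p, ], "+")
            ok <- q[, 1] >= 1 & q[, 1] <= d[1] &
                  q[, 2] >= 1 & q[, 2] <= d[2] &
                  q[, 3] >= 1 & q[, 3] <= d[3]
            ql <- q[ok, 1] + (q[ok, 2] - 1) * d[1] + (q[ok, 3] - 1) * d[1] * d[2]
            ql <- ql[eligible[ql] & labels[ql] == 0L]
            labels[ql] <- cur
            stack <- c(stack, ql)
        }
    }
    labels
}

# threshold-then-select-components region growing oracle
oracleGrow <- function(values, threshold, seeds, confine, connectivity) {
    d <- dim(values)
    eligible <- confine & (values >= threshold)
    labels <- oracleLabelComponents(eligible, connectivity)
    sl <- seeds[, 1] + (seeds[, 2] - 1) * d[1] + (seeds[, 3] - 1) * d[1] * d[2]
    keep <- setdiff(unique(labels[sl]), 0L)
    array(labels %in% keep & labels > 0L, d)
}

# all-pairs directed average Hausdorff distance, direct formula
oracleDirectedAHD <- function(m1, m2, spacing) {
    A <- (which(m1, arr.ind = TRUE) - 1) %*% diag(spacing)
    B <- (which(m2, arr.ind = TRUE) - 1) %*% diag(spacing)
    total <- 0
    for (i in seq_len(nrow(A))) {
        dd <- sqrt((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 +
                   (A[i, 3] - B[, 3])^2)
        total <- total + min(dd)
    }
    total / nrow(A)
}

# step-by-step greedy hottest-N simulation recomputing the frontier from
# scratch at every step
oracleGreedyHotspot <- function(values, region, n, connectivity) {
    d <- dim(values)
    offs <- oracleOffsets(connectivity)
    allIJK <- arrayInd(seq_len(prod(d)), d)
    regionIdx <- which(region)
    seed <- regionIdx[order(-values[regionIdx], regionIdx)][1]
    mask <- array(FALSE, d)
    mask[seed] <- TRUE
    while (sum(mask) < min(n, length(regionIdx))) {
        frontier <- integer()
        for (p in which(mask)) {
            q <- sweep(offs, 2L, allIJK[p, ], "+")
            ok <- q[, 1] >= 1 & q[, 1] <= d[1] &
                  q[, 2] >= 1 & q[, 2] <= d[2] &
                  q[, 3] >= 1 & q[, 3] <= d[3]
            ql <- q[ok, 1] + (q[ok, 2] - 1) * d[1] + (q[ok, 3] - 1) * d[1] * d[2]
            frontier <- c(frontier, ql[region[ql] & !mask[ql]])
        }
        frontier <- unique(frontier)
        if (length(frontier) == 0L) break
        mask[frontier[order(-values[frontier], frontier)][1]] <- TRUE
    }
    mask
}

# random small binary mask on a grid
randomMask <- function(d, maxVoxels, spacing = c(1, 1, 1)) {
    n <- sample.int(maxVoxels, 1L)
    m <- array(FALSE, d)
    m[sample.int(prod(d), n)] <- TRUE
    maskVolume(m, spacing)
}

# smooth-ish random image: white noise plus a few random gaussian bumps,
# so thresholding yields nontrivial connected structure
randomStructuredImage <- function(d, spacing = c(1, 1, 1)) {
    v <- array(rnorm(prod(d), 0, 0.3), d)
    for (b in seq_len(sample(2:4, 1L))) {
        ctr <- runif(3, 2, d - 1)
        sig <- runif(1, 1, 3)
        u <- lapply(1:3, function(ax)
            ((seq_len(d[ax]) - ctr[ax]) / sig)^2)
        v <- v + runif(1, 0.5, 2) *
            exp(-0.5 * outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+"))
    }
    voxelGrid(v, spacing)
}

fullMask <- function(d, spacing = c(1, 1, 1)) {
    maskVolume(array(TRUE, d), spacing)
}

# compact default phantom used by several suites: one gaussian lesion,
# offset PET-B and CE centres available on demand
smallPhantomSpec <- function(seed = 7L, rho = 0.8, offsetMm = c(0, 0, 0),
                             ceOffsetMm = c(0, 0, 0), noise = TRUE,
                             textureCV = 0.25, profile = "gaussian",
                             radiiMm = 14, grid = c(48L, 48L, 48L),
                             enhancementFactor = 1) {
    # centre on a voxel centre near the grid middle (an exact half-voxel
    # position would create intensity ties and an ambiguous argmax)
    ctr <- (grid %/% 2) * c(2.036, 2.036, 2.027)
    phantomSpec(
        gridShape = grid,
        lesions = list(lesionSpec(
            center = ctr, radiiMm = radiiMm, profile = profile,
            centerByModality = list(pet_aa = ctr + offsetMm,
                                    ce = ctr + ceOffsetMm))),
        rhoTarget = rho,
        noiseSd = if (noise) c(pet_tspo = 0.05, pet_aa = 0.05,
                               t1_native = 5, t2 = 5)
                  else c(pet_tspo = 0, pet_aa = 0, t1_native = 0, t2 = 0),
        textureCV = textureCV,
        enhancementFactor = enhancementFactor,
        seed = seed)
}
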