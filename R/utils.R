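# Internal helpers shared across modules: neighbourhood offsets, array
# shifting for vectorised flood fill, index conversions and grid checks.

.connOffsets <- function(connectivity = c("face", "full")) {
    connectivity <- match.arg(connectivity)
    if (connectivity == "face") {
        off <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                     c(0L, -1L, 0L), c(0L, 1L, 0L),
                     c(0L, 0L, -1L), c(0L, 0L, 1L))
    } else {
        g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
        off <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    }
    storage.mode(off) <- "integer"
    dimnames(off) <- NULL
    off
}

# result[i,j,k] = a[i - off[1], j - off[2], k - off[3]]; out-of-range -> fill
.shift3d <- function(a, off, fill) {
    d <- dim(a)
    out <- array(fill, d)
    dst <- src <- vector("list", 3L)
    for (ax in 1:3) {
        o <- off[ax]
        if (o >= 0L) {
            if (o >= d[ax]) return(out)
            dst[[ax]] <- (o + 1L):d[ax]
            src[[ax]] <- 1L:(d[ax] - o)
        } else {
            if (-o >= d[ax]) return(out)
            dst[[ax]] <- 1L:(d[ax] + o)
            src[[ax]] <- (1L - o):d[ax]
        }
    }
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
    out
}

# one wavefront step of binary dilation restricted to eligible voxels
.growOnce <- function(visited, eligible, offsets) {
    grown <- visited
    for (r in seq_len(nrow(offsets)))
        grown <- grown | .shift3d(visited, offsets[r, ], FALSE)
    grown & eligible
}

.linIndex <- function(idx, d) {
    as.integer(idx[, 1L] + (idx[, 2L] - 1L) * d[1L] +
               (idx[, 3L] - 1L) * d[1L] * d[2L])
}

# linear indices of in-bounds neighbours of a single voxel
.voxelNeighbours <- function(lin, d, offsets) {
    ijk <- arrayInd(lin, d)
    nb <- sweep(offsets, 2L, as.integer(ijk), "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    .linIndex(nb[ok, , drop = FALSE], d)
}

# physical voxel-centre coordinates in mm; origin at voxel (1,1,1)
.voxelCoordsMm <- function(idx, spacingMm) {
    sweep(idx - 1L, 2L, spacingMm, "*")
}

.spacingOf <- function(x) {
    if (is(x, "VoxelGrid")) x@spacing
    else if (is(x, "MaskVolume")) x@spacing
    else stop("cannot extract spacing from a ", class(x))
}

.dimOf <- function(x) {
    if (is(x, "VoxelGrid")) dim(x@values)
    else if (is(x, "MaskVolume")) dim(x@membership)
    else stop("cannot extract dimensions from a ", class(x))
}

# shapes must be identical; spacings equal within 1e-3 relative tolerance
.checkSameGrid <- function(x, y, xName = "first", yName = "second",
                           tol = 1e-3) {
    dx <- .dimOf(x); dy <- .dimOf(y)
    sx <- .spacingOf(x); sy <- .spacingOf(y)
    if (!identical(dx, dy) || any(abs(sx - sy) > tol * pmax(sx, sy))) {
        stop(sprintf(
            "grid mismatch: %s is %s @ (%s) mm but %s is %s @ (%s) mm",
            xName, paste(dx, collapse = "x"),
            paste(format(sx, digits = 6), collapse = ", "),
            yName, paste(dy, collapse = "x"),
            paste(format(sy, digits = 6), collapse = ", ")))
    }
    invisible(TRUE)
}

.asSeedMatrix <- function(seeds) {
    if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1L)
    if (ncol(seeds) != 3L)
        stop("seeds must be a matrix of voxel indices with 3 columns")
    storage.mode(seeds) <- "integer"
    seeds
}
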