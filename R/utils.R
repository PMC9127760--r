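# Internal numerical helpers shared across modules.

# Default voxel-to-mm affine for a given voxel size (mm), origin at the
# grid corner.
identityAffine <- function(voxelSizeMM = c(3, 3, 3)) {
    a <- diag(c(voxelSizeMM, 1))
    storage.mode(a) <- "double"
    a
}

# Voxel sizes (mm per voxel) along the three axes, from the affine.
voxelSizes <- function(affine) {
    sqrt(colSums(affine[1:3, 1:3]^2))
}

# Sum of each element and its two along-axis neighbors (zero padding),
# applied to a 3D or 4D array. Three successive calls give the 27-voxel
# box sum.
axisNeighborSum <- function(a, axis) {
    d <- dim(a)
    nd <- length(d)
    perm <- c(axis, setdiff(seq_len(nd), axis))
    x <- if (axis == 1L) a else aperm(a, perm)
    dm <- dim(x)
    dim(x) <- c(dm[1], prod(dm[-1]))
    n <- nrow(x)
    out <- x
    out[-1, ] <- out[-1, ] + x[-n, ]
    out[-n, ] <- out[-n, ] + x[-1, ]
    dim(out) <- dm
    if (axis != 1L) out <- aperm(out, order(perm))
    out
}

boxSum27 <- function(a) {
    axisNeighborSum(axisNeighborSum(axisNeighborSum(a, 1L), 2L), 3L)
}

# 1D Gaussian convolution along one axis of a 3D array, zero padding.
axisGaussFilter <- function(a, kernel, axis) {
    r <- (length(kernel) - 1L) %/% 2L
    d <- dim(a)
    nd <- length(d)
    perm <- c(axis, setdiff(seq_len(nd), axis))
    x <- if (axis == 1L) a else aperm(a, perm)
    dm <- dim(x)
    dim(x) <- c(dm[1], prod(dm[-1]))
    n <- nrow(x)
    out <- kernel[r + 1L] * x
    if (r > 0) for (o in seq_len(r)) {
        k <- kernel[r + 1L + o]
        out[seq_len(n - o), ] <- out[seq_len(n - o), ] +
            k * x[seq_len(n - o) + o, ]
        out[seq_len(n - o) + o, ] <- out[seq_len(n - o) + o, ] +
            k * x[seq_len(n - o), ]
    }
    dim(out) <- dm
    if (axis != 1L) out <- aperm(out, order(perm))
    out
}

# Samples from a normal truncated below at `lower`, by inverse-CDF.
rtruncnormLower <- function(n, mean, sd, lower) {
    if (n == 0L) return(numeric(0))
    plo <- stats::pnorm((lower - mean) / sd)
    stats::qnorm(stats::runif(n, plo, 1)) * sd + mean
}

# Mean of N(mu, sd) truncated below at `lower`.
truncnormMean <- function(mu, sd, lower) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
}

# Location parameter mu* such that the lower-truncated normal with the
# given sd has the requested mean. Used so that simulated clinical
# scales reproduce printed cohort means despite hard floors.
matchTruncnormMean <- function(target, sd, lower) {
    if ((target - lower) / sd > 8) return(target)   # shift negligible
    f <- function(mu) truncnormMean(mu, sd, lower) - target
    stats::uniroot(f, lower = target - 6 * sd, upper = target + sd,
                   tol = 1e-10)$root
}

# Deterministic sub-seed derivation (kept below 2^31).
deriveSeeds <- function(seed, n) {
    as.integer((as.double(seed) %% 2147483647 + 7919 * seq_len(n)) %%
               2147483647)
}

# Average-rank of each column of a T x V matrix. Fast path: one radix
# sort over (column, value) ranks every column at once; columns with
# ties (repeated values, measure-zero for BOLD floats) fall back to
# rank() for the average-tie convention.
columnRanks <- function(x) {
    tt <- nrow(x); v <- ncol(x)
    if (tt == 0L || v == 0L) return(x)
    ord <- order(col(x), x)
    r <- numeric(tt * v)
    r[ord] <- rep.int(seq_len(tt), v)
    sorted <- x[ord]
    dim(sorted) <- c(tt, v)
    tied <- which(colSums(sorted[-1L, , drop = FALSE] ==
                          sorted[-tt, , drop = FALSE]) > 0)
    r <- matrix(r, tt, v)
    for (j in tied) r[, j] <- rank(x[, j], ties.method = "average")
    r
}

# Ordered in-mask voxel coordinates: lexicographic by (i, j, k).
maskCoordinates <- function(mask) {
    co <- which(mask, arr.ind = TRUE)
    co <- co[order(co[, 1], co[, 2], co[, 3]), , drop = FALSE]
    storage.mode(co) <- "integer"
    dimnames(co) <- NULL
    co
}

`%||%` <- function(x, y) if (is.null(x)) y else x
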