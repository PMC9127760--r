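#' Kendall's coefficient of concordance for a set of time series
#'
#' W = (sum_i R_i^2 - n * Rbar^2) / ((1/12) K^2 (n^3 - n)), where the
#' K rows are ranked independently in time, R_i is the across-series
#' sum of ranks at time point i, and Rbar = (n + 1) K / 2. W is 1 iff
#' all series are rank-identical and 0 under no concordance. Ties take
#' average ranks; a fully constant set returns 0 with a warning.
#'
#' @param timeSeriesSet K x n numeric matrix: K series of n time points.
#' @return W in \[0, 1\].
#' @examples
#' computeKCC(rbind(1:4, 1:4, 4:1))  # 5/45
#' @export
computeKCC <- function(timeSeriesSet) {
    x <- as.matrix(timeSeriesSet)
    k <- nrow(x); n <- ncol(x)
    if (k < 2L || n < 2L)
        stop("computeKCC: need K >= 2 series and n >= 2 time points")
    if (all(x == x[, 1])) {
        warning("computeKCC: all series constant; W undefined, returning 0")
        return(0)
    }
    ranks <- t(apply(x, 1L, rank, ties.method = "average"))
    ri <- colSums(ranks)
    rbar <- (n + 1) * k / 2
    num <- sum(ri^2) - n * rbar^2
    den <- k * k * (n^3 - n) / 12
    w <- num / den
    min(max(w, 0), 1)
}

#' Voxelwise regional homogeneity map
#'
#' For every in-mask voxel, Kendall's W over the voxel and the in-mask
#' subset of its 26 face/edge/corner neighbors (K = 1 + neighbor count;
#' 27 in the interior). Voxels with K < 2, and voxels outside the mask,
#' are 0. Computed by summing per-voxel temporal rank arrays over the
#' 3 x 3 x 3 neighborhood, which is algebraically identical to the
#' per-voxel definition.
#'
#' @param series a [BoldSeries-class] object.
#' @param mask logical 3D array matching the spatial grid. Default: all
#'   voxels.
#' @param requireFullNeighborhood if TRUE, voxels whose 27-voxel
#'   neighborhood is not fully inside the mask are set to 0 instead of
#'   using the in-mask subset.
#' @return a [ReHoMap-class] object at stage "raw".
#' @export
rehoMap <- function(series, mask = NULL,
                    requireFullNeighborhood = FALSE) {
    d <- dim(series@data)[1:3]
    tt <- dim(series@data)[4]
    if (is.null(mask)) mask <- array(TRUE, dim = d)
    if (!identical(dim(mask), d))
        stop("rehoMap: mask shape does not match the spatial grid")
    if (!any(mask)) stop("rehoMap: mask is empty")
    storage.mode(mask) <- "logical"

    y <- seriesMatrix(series)              # T x V
    mvec <- as.vector(mask)
    ranks <- matrix(0, tt, prod(d))
    ranks[, mvec] <- columnRanks(y[, mvec, drop = FALSE])
    ranks <- t(ranks)                      # voxel-major for reshaping
    dim(ranks) <- c(d, tt)

    kcount <- boxSum27(array(as.numeric(mask), dim = d))
    rsum <- boxSum27(ranks)                # per-voxel R_i, all t
    dim(rsum) <- c(prod(d), tt)
    s2 <- rowSums(rsum^2)

    k <- as.vector(kcount)
    rbar <- (tt + 1) * k / 2
    num <- s2 - tt * rbar^2
    den <- k * k * (tt^3 - tt) / 12
    w <- ifelse(den > 0, num / den, 0)
    w[!mvec | k < 2] <- 0
    w <- pmin(pmax(w, 0), 1)
    if (requireFullNeighborhood)
        w[k < 27] <- 0
    vals <- array(w, dim = d)
    new("ReHoMap", values = vals, mask = mask, stage = "raw",
        affine = series@affine, subjectID = series@subjectID)
}

#' Divide a ReHo map by its within-mask global mean
#'
#' Removes inter-individual scale differences; the in-mask mean of the
#' result is exactly 1.
#'
#' @param map a [ReHoMap-class] object (stage "raw").
#' @return a [ReHoMap-class] at stage "normalized".
#' @export
normalizeGlobalMean <- function(map) {
    g <- mean(map@values[map@mask])
    if (!is.finite(g) || g <= 0)
        stop("normalizeGlobalMean: in-mask mean must be positive")
    vals <- map@values / g
    vals[!map@mask] <- 0
    # pin the in-mask mean to 1 exactly (guards the class invariant
    # against the last-ulp rounding of the division)
    vals[map@mask] <- vals[map@mask] / mean(vals[map@mask])
    new("ReHoMap", values = vals, mask = map@mask, stage = "normalized",
        affine = map@affine, subjectID = map@subjectID)
}

#' Gaussian smoothing of a ReHo map
#'
#' Separable 3D Gaussian convolution with per-axis sigma =
#' FWHM / sqrt(8 ln 2) converted from mm to voxels via the affine.
#' Edge-renormalized (convolution of the field divided by convolution
#' of ones), so constant maps are preserved; the result is re-masked.
#'
#' @param map a [ReHoMap-class] object (stage "normalized").
#' @param fwhmMM full-width at half-maximum in mm (default 4).
#' @return a [ReHoMap-class] at stage "smoothed".
#' @export
smoothGaussian <- function(map, fwhmMM = 4) {
    if (fwhmMM <= 0) {
        warning("smoothGaussian: fwhmMM <= 0; returning the map unsmoothed")
        return(new("ReHoMap", values = map@values, mask = map@mask,
                   stage = "smoothed", affine = map@affine,
                   subjectID = map@subjectID))
    }
    vs <- voxelSizes(map@affine)
    sigmaVox <- fwhmMM / sqrt(8 * log(2)) / vs
    vals <- map@values
    ones <- array(1, dim = dim(vals))
    for (ax in 1:3) {
        r <- max(1L, ceiling(4 * sigmaVox[ax]))
        kern <- exp(-((-r:r)^2) / (2 * sigmaVox[ax]^2))
        kern <- kern / sum(kern)
        vals <- axisGaussFilter(vals, kern, ax)
        ones <- axisGaussFilter(ones, kern, ax)
    }
    vals <- vals / ones
    vals[!map@mask] <- 0
    new("ReHoMap", values = vals, mask = map@mask, stage = "smoothed",
        affine = map@affine, subjectID = map@subjectID)
}

#' Full ReHo chain for one subject
#'
#' [rehoMap()], then [normalizeGlobalMean()], then [smoothGaussian()]:
#' the smoothed standardized map (smReHo) used as classifier input.
#'
#' @inheritParams rehoMap
#' @inheritParams smoothGaussian
#' @return a [ReHoMap-class] at stage "smoothed".
#' @export
smReHo <- function(series, mask = NULL, fwhmMM = 4) {
    smoothGaussian(normalizeGlobalMean(rehoMap(series, mask)), fwhmMM)
}

#' @describeIn rehoMap map value accessor
#' @param map a [ReHoMap-class] object.
#' @export
mapValues <- function(map) map@values

#' @describeIn rehoMap map mask accessor
#' @export
mapMask <- function(map) map@mask

#' @describeIn rehoMap processing-stage accessor
#' @export
mapStage <- function(map) map@stage
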