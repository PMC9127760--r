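#' Permutation test of classification performance
#'
#' Repeats the full leave-one-subject-out procedure under uniformly
#' permuted labels and counts how often each permuted performance
#' metric is equal to or higher than the observed one; the p-value is
#' that count divided by the number of permutations. A count of zero is
#' displayed as "p < 1/nPerm" (e.g. p < 0.001 at 1,000 permutations).
#' Label permutation preserves the group sizes by construction.
#'
#' @inheritParams losocv
#' @param nPerm number of label permutations (>= 1; the study-scale
#'   convention is 1,000).
#' @param seed integer seed for the permutation stream.
#' @param keepWeights also record the across-fold mean voxel weights of
#'   every permuted run (needed for [permuteVoxelWeights()]).
#' @return a [PermutationResult-class] object.
#' @export
permutePerformance <- function(features, labels,
                               algorithm = c("svm", "bgpc", "mgpc"),
                               nPerm = 1000L, seed = 1L,
                               positiveClass = NULL, cParam = 1,
                               keepWeights = FALSE) {
    algorithm <- match.arg(algorithm)
    if (nPerm < 1L) stop("permutePerformance: 'nPerm' must be >= 1")
    x <- if (is(features, "FeatureMatrix")) features@values else
         as.matrix(features)
    y <- as.character(labels)
    obsCV <- losocv(x, y, algorithm, positiveClass, cParam,
                    keepWeights = keepWeights)
    obs <- unlist(obsCV@metrics[metricNamesFor(obsCV)])

    nullVals <- matrix(NA_real_, nPerm, length(obs),
                       dimnames = list(NULL, names(obs)))
    nullW <- if (keepWeights) matrix(0, nPerm, ncol(x)) else
             matrix(0, 0, 0)
    set.seed(as.integer(seed))
    for (b in seq_len(nPerm)) {
        yp <- sample(y)
        cvb <- losocv(x, yp, algorithm, positiveClass, cParam,
                      keepWeights = keepWeights)
        nullVals[b, ] <- unlist(cvb@metrics[metricNamesFor(cvb)])
        if (keepWeights) nullW[b, ] <- colMeans(cvb@foldWeights)
    }
    counts <- colSums(sweep(nullVals, 2L, obs, `>=`), na.rm = TRUE)
    pv <- counts / nPerm
    new("PermutationResult", observed = obs, nullValues = nullVals,
        pValues = pv, nPerm = as.integer(nPerm),
        seed = as.integer(seed),
        observedWeights = if (keepWeights) colMeans(obsCV@foldWeights)
                          else numeric(0),
        nullWeights = nullW)
}

metricNamesFor <- function(cv) {
    if (length(cv@classes) == 2L)
        c("total_accuracy", "balanced_accuracy", "sensitivity",
          "specificity")
    else c("total_accuracy", "balanced_accuracy")
}

#' Format a permutation p-value
#'
#' Zero counts are reported as "< 1/nPerm" rather than 0, matching the
#' usual "p < 0.001" convention at 1,000 permutations.
#'
#' @param p numeric p-value(s) from a permutation test.
#' @param nPerm number of permutations behind the value.
#' @return character vector.
#' @examples
#' formatPermutationP(0, 1000)   # "p < 0.001"
#' @export
formatPermutationP <- function(p, nPerm) {
    ifelse(p == 0, paste0("p < ", format(1 / nPerm, scientific = FALSE)),
           paste0("p = ", format(p, scientific = FALSE)))
}

#' Per-voxel permutation p-values of discriminative weights
#'
#' The contribution statistic of a voxel is the absolute across-fold
#' mean weight of its run's *unit-norm* weight map; the p-value is the
#' fraction of permuted runs whose statistic is equal to or larger
#' than the observed one. The per-run normalization is essential, not
#' cosmetic: a maximum-margin classifier fits a well-separated (real)
#' effect with a *small-norm* weight vector (the norm is inversely
#' proportional to the margin), whereas permuted labels give
#' non-separable problems whose dual variables sit at the cost bound
#' and inflate every weight. Comparing raw magnitudes would therefore
#' favor the null; comparing relative contributions asks where the
#' discriminative direction points, independent of its scale.
#'
#' @param observedWeights length-V observed mean weight vector.
#' @param nullWeights nPerm x V matrix of permuted mean weights.
#' @param normalize divide each run's weight vector by its L2 norm
#'   before comparison (default TRUE; FALSE gives the raw-magnitude
#'   variant).
#' @return length-V vector of p-values in \[0, 1\].
#' @export
permuteVoxelWeights <- function(observedWeights, nullWeights,
                                normalize = TRUE) {
    if (!length(observedWeights) || !nrow(nullWeights))
        stop("permuteVoxelWeights: permuted weights are missing; run ",
             "permutePerformance(..., keepWeights = TRUE)")
    if (ncol(nullWeights) != length(observedWeights))
        stop("permuteVoxelWeights: voxel count mismatch between ",
             "observed and permuted weights")
    if (normalize) {
        unitize <- function(v) {
            nv <- sqrt(sum(v^2))
            if (nv > 0) v / nv else v
        }
        observedWeights <- unitize(observedWeights)
        nullWeights <- t(apply(nullWeights, 1L, unitize))
    }
    colMeans(sweep(abs(nullWeights), 2L, abs(observedWeights), `>=`))
}

connectivityOffsets <- function(connectivity) {
    off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    off <- off[rowSums(off != 0) > 0, , drop = FALSE]
    d <- rowSums(abs(off))
    keep <- switch(as.character(connectivity),
                   "6" = d == 1, "18" = d <= 2, "26" = rep(TRUE, 26),
                   stop("extractClusters: connectivity must be 6, 18 or 26"))
    off[keep, , drop = FALSE]
}

#' Suprathreshold clusters of a discriminative map
#'
#' Thresholds the voxel p-map at p < alpha, labels connected components
#' under the chosen neighborhood, and keeps components strictly larger
#' than the extent cutoff. Each surviving cluster is signed by the mean
#' classifier weight over its voxels and carries the peak (largest-|w|)
#' coordinate.
#'
#' @param voxelP 3D array of per-voxel p-values.
#' @param meanWeight 3D array of mean classifier weights.
#' @param alpha voxel threshold (default 0.001, the study-scale level
#'   at 1,000 permutations).
#' @param minCluster extent cutoff; components must exceed it strictly
#'   (default 30 voxels: a 30-voxel component is excluded, a 31-voxel
#'   one kept).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask optional logical 3D array restricting the search.
#' @return list of [ClusterROI-class] objects (possibly empty), ordered
#'   by decreasing size.
#' @export
extractClusters <- function(voxelP, meanWeight, alpha = 0.001,
                            minCluster = 30L, connectivity = 26L,
                            mask = NULL) {
    d <- dim(voxelP)
    if (!identical(d, dim(meanWeight)))
        stop("extractClusters: maps do not share a grid")
    off <- connectivityOffsets(connectivity)
    cand <- voxelP < alpha
    if (!is.null(mask)) cand <- cand & mask
    candIdx <- which(cand)
    if (!length(candIdx)) return(list())

    labels <- array(0L, dim = d)
    labels[candIdx] <- -1L                 # unvisited candidate
    strideJ <- d[1]; strideK <- d[1] * d[2]
    offLin <- off[, 1] + off[, 2] * strideJ + off[, 3] * strideK
    coordOf <- function(lin) {
        lin0 <- lin - 1L
        cbind(lin0 %% d[1] + 1L,
              (lin0 %/% d[1]) %% d[2] + 1L,
              lin0 %/% strideK + 1L)
    }
    clusters <- list()
    nextLab <- 0L
    for (s in candIdx) {
        if (labels[s] != -1L) next
        nextLab <- nextLab + 1L
        members <- integer(0)
        frontier <- s
        labels[s] <- nextLab
        while (length(frontier)) {
            members <- c(members, frontier)
            co <- coordOf(frontier)
            nb <- rep(frontier, each = nrow(off)) +
                  rep(offLin, length(frontier))
            # reject neighbors that wrapped around a grid edge
            nbco <- co[rep(seq_len(nrow(co)), each = nrow(off)), ,
                       drop = FALSE] +
                    off[rep(seq_len(nrow(off)), nrow(co)), , drop = FALSE]
            ok <- nbco[, 1] >= 1 & nbco[, 1] <= d[1] &
                  nbco[, 2] >= 1 & nbco[, 2] <= d[2] &
                  nbco[, 3] >= 1 & nbco[, 3] <= d[3]
            nb <- unique(nb[ok])
            nb <- nb[labels[nb] == -1L]
            labels[nb] <- nextLab
            frontier <- nb
        }
        if (length(members) > minCluster) {
            co <- coordOf(sort(members))
            wvals <- meanWeight[co]
            peak <- co[which.max(abs(wvals)), ]
            sgn <- if (mean(wvals) >= 0) "positive" else "negative"
            clusters[[length(clusters) + 1L]] <-
                new("ClusterROI", voxels = co, peak = as.integer(peak),
                    sign = sgn, label = "")
        }
    }
    ord <- order(vapply(clusters, function(cl) nrow(cl@voxels),
                        numeric(1)), decreasing = TRUE)
    clusters <- clusters[ord]
    for (i in seq_along(clusters))
        clusters[[i]]@label <- sprintf("cluster%02d_%s", i,
            if (clusters[[i]]@sign == "positive") "pos" else "neg")
    clusters
}

#' Build the discriminative map for a binary classification
#'
#' Combines the observed across-fold mean weights, the per-voxel
#' permutation p-values and the surviving clusters into one object.
#'
#' @param permResult a [PermutationResult-class] run with
#'   `keepWeights = TRUE`.
#' @param features the [FeatureMatrix-class] behind the classification.
#' @inheritParams extractClusters
#' @return a [DiscriminativeMap-class] object.
#' @export
discriminativeMap <- function(permResult, features, alpha = 0.001,
                              minCluster = 30L, connectivity = 26L) {
    pvox <- permuteVoxelWeights(permResult@observedWeights,
                                permResult@nullWeights)
    mask <- array(FALSE, dim = features@gridDim)
    mask[features@voxelIndex] <- TRUE
    pArr <- array(1, dim = features@gridDim)
    pArr[features@voxelIndex] <- pvox
    wArr <- weightsToMap(permResult@observedWeights, features)
    clusters <- extractClusters(pArr, wArr, alpha, minCluster,
                                connectivity, mask)
    new("DiscriminativeMap", meanWeight = wArr, voxelP = pArr,
        mask = mask, clusters = clusters, alpha = alpha,
        minClusterVoxels = as.integer(minCluster),
        nPerm = permResult@nPerm, affine = features@affine)
}

#' Cluster summary table
#'
#' @param dmap a [DiscriminativeMap-class] object.
#' @return data.frame with label, size, sign, peak grid (0-based) and
#'   mm coordinates.
#' @export
clusterTable <- function(dmap) {
    rows <- lapply(dmap@clusters, function(cl) {
        mm <- dmap@affine %*% c(cl@peak - 1L, 1)
        data.frame(label = cl@label, size = nrow(cl@voxels),
                   sign = cl@sign,
                   peak_i = cl@peak[1] - 1L, peak_j = cl@peak[2] - 1L,
                   peak_k = cl@peak[3] - 1L,
                   peak_x_mm = mm[1], peak_y_mm = mm[2],
                   peak_z_mm = mm[3])
    })
    if (!length(rows))
        return(data.frame(label = character(0), size = integer(0),
                          sign = character(0), peak_i = integer(0),
                          peak_j = integer(0), peak_k = integer(0),
                          peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                          peak_z_mm = numeric(0)))
    do.call(rbind, rows)
}
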