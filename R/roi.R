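#' Per-subject mean smReHo over discriminative clusters
#'
#' Entry (s, r) is the arithmetic mean of subject s's map over cluster
#' r's voxels.
#'
#' @param maps list of [ReHoMap-class] objects (stage "smoothed").
#' @param clusters list of [ClusterROI-class] objects sharing the grid.
#' @return subjects x ROI matrix with subject ids as row names and
#'   cluster labels as column names.
#' @export
extractRoiMeans <- function(maps, clusters) {
    if (!length(clusters)) stop("extractRoiMeans: no clusters supplied")
    for (cl in clusters)
        if (!nrow(cl@voxels))
            stop("extractRoiMeans: empty cluster '", cl@label, "'")
    out <- vapply(clusters, function(cl)
        vapply(maps, function(m) mean(m@values[cl@voxels]), numeric(1)),
        numeric(length(maps)))
    out <- matrix(out, nrow = length(maps),
                  dimnames = list(vapply(maps, function(m) m@subjectID,
                                         character(1)),
                                  vapply(clusters, function(cl) cl@label,
                                         character(1))))
    out
}

#' Partial Pearson correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of x and y after each is
#' regressed on \[intercept | covariates\]; the test statistic is
#' t = r sqrt(df / (1 - r^2)) with df = n - k - 2 (k covariates),
#' two-tailed. With no covariates this is exactly the plain Pearson
#' correlation and its usual t-test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (n x k) or NULL.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partialPearson <- function(x, y, covariates = NULL) {
    n <- length(x)
    if (length(y) != n) stop("partialPearson: length mismatch")
    k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
    if (n <= k + 2L)
        stop("partialPearson: need n > #covariates + 2")
    design <- cbind(rep(1, n), covariates)
    qrd <- qr(design)
    rx <- qr.resid(qrd, x)
    ry <- qr.resid(qrd, y)
    if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
        warning("partialPearson: residuals are constant; ",
                "correlation undefined")
        return(list(r = NA_real_, p = NA_real_, df = n - k - 2L, n = n))
    }
    r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    df <- n - k - 2L
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
    list(r = r, p = p, df = df, n = n)
}

#' Bonferroni-corrected significance threshold
#'
#' Default mode divides alpha by the number of tests m. The "pairwise"
#' mode divides by m(m-1)/2 (the all-pairs comparison count sometimes
#' quoted for a set of m ROIs).
#'
#' @param alpha family-wise level (e.g. 0.05).
#' @param m number of tests (>= 1).
#' @param mode "tests" (alpha/m) or "pairwise" (alpha/(m(m-1)/2)).
#' @return corrected per-test threshold.
#' @examples
#' bonferroniThreshold(0.05, 18)              # 0.002778
#' bonferroniThreshold(0.05, 18, "pairwise")  # 0.05/153
#' @export
bonferroniThreshold <- function(alpha, m, mode = c("tests", "pairwise")) {
    mode <- match.arg(mode)
    if (m < 1L) stop("bonferroniThreshold: 'm' must be >= 1")
    if (mode == "tests") alpha / m
    else alpha / (m * (m - 1) / 2)
}

#' Z-transform a score vector
#'
#' Centers to mean 0 and scales to sample SD 1 (denominator n - 1).
#' Idempotent up to floating precision.
#'
#' @param scores numeric vector (length >= 2, nonzero variance).
#' @return standardized vector.
#' @export
zTransform <- function(scores) {
    if (length(scores) < 2L)
        stop("zTransform: need at least 2 values")
    s <- stats::sd(scores)
    if (!is.finite(s) || s == 0)
        stop("zTransform: zero variance")
    (scores - mean(scores)) / s
}

#' ROI-wise partial correlation against symptom severity
#'
#' Runs [partialPearson()] of every ROI column against the severity
#' score with the given covariates, and flags ROIs passing the
#' Bonferroni-corrected threshold.
#'
#' @param roiTable subjects x ROI matrix (see [extractRoiMeans()]).
#' @param severity numeric severity score per subject (z-transformed
#'   internally for reporting; correlation is scale-invariant).
#' @param covariates numeric matrix of per-subject covariates or NULL.
#' @param alpha family-wise level.
#' @param bonferroniMode "tests" or "pairwise" (see
#'   [bonferroniThreshold()]).
#' @return data.frame with roi, r, p, df, threshold and pass flag.
#' @export
roiCorrelation <- function(roiTable, severity, covariates = NULL,
                           alpha = 0.05,
                           bonferroniMode = c("tests", "pairwise")) {
    bonferroniMode <- match.arg(bonferroniMode)
    m <- ncol(roiTable)
    thr <- bonferroniThreshold(alpha, m, bonferroniMode)
    rows <- lapply(seq_len(m), function(j) {
        res <- partialPearson(roiTable[, j], severity, covariates)
        data.frame(roi = colnames(roiTable)[j] %||% paste0("roi", j),
                   r = res$r, p = res$p, df = res$df,
                   threshold = thr,
                   significant = !is.na(res$p) && res$p < thr)
    })
    do.call(rbind, rows)
}
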