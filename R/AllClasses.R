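#' @import methods
NULL

#' One subject's 4D BOLD series
#'
#' Container for a spatially normalized resting-state BOLD acquisition:
#' an X x Y x Z x T array together with the repetition time and the
#' voxel-to-mm affine. The series is assumed to be the *retained* part of
#' the acquisition (dummy volumes already discarded).
#'
#' @slot data numeric 4D array (X x Y x Z x T), arbitrary signal units.
#' @slot trSeconds repetition time in seconds.
#' @slot affine 4 x 4 voxel-to-mm transform.
#' @slot subjectID subject identifier.
#'
#' @seealso [boldSeries()], [rehoMap()], [preprocessBold()]
#' @export
setClass("BoldSeries",
    representation(data = "array", trSeconds = "numeric",
                   affine = "matrix", subjectID = "character"))

setValidity("BoldSeries", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L)
        return("'data' must be a 4D array (X x Y x Z x T)")
    if (d[4] < 20L)
        return("need at least 20 time points (T >= 20)")
    if (!all(is.finite(object@data)))
        return("'data' contains non-finite values")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
        return("'trSeconds' must be a single positive number")
    if (!all(dim(object@affine) == c(4L, 4L)))
        return("'affine' must be a 4 x 4 matrix")
    TRUE
})

#' Nuisance regressor set for one subject
#'
#' Holds the Friston-24 expansion of the six rigid-body realignment
#' parameters plus the white-matter, CSF and whole-brain mean signals.
#' Any of the signal slots may be length zero (absent), in which case it
#' is omitted from the design matrix.
#'
#' @slot motion24 T x 24 matrix: \{p, p^2, p(t-1), p(t-1)^2\} for the six
#'   base parameters; lagged terms are 0 in the first row.
#' @slot wm,csf,global length-T vectors (or length 0 if absent).
#'
#' @seealso [confoundSet()], [regressConfounds()]
#' @export
setClass("ConfoundSet",
    representation(motion24 = "matrix", wm = "numeric", csf = "numeric",
                   global = "numeric"))

setValidity("ConfoundSet", function(object) {
    tt <- nrow(object@motion24)
    if (ncol(object@motion24) != 24L && ncol(object@motion24) != 0L)
        return("'motion24' must have 24 columns")
    for (nm in c("wm", "csf", "global")) {
        v <- slot(object, nm)
        if (length(v) && tt && length(v) != tt)
            return(sprintf("'%s' length does not match motion24 rows", nm))
    }
    TRUE
})

#' Voxelwise regional homogeneity map
#'
#' A 3D map of Kendall's coefficient of concordance (W) computed per
#' voxel over its 27-voxel neighborhood, at one of three stages:
#' \describe{
#'   \item{raw}{W in \[0, 1\] inside the mask, 0 outside.}
#'   \item{normalized}{raw values divided by the within-mask mean
#'     (in-mask mean of the result is 1).}
#'   \item{smoothed}{normalized map after Gaussian smoothing (smReHo).}
#' }
#'
#' @slot values numeric 3D array.
#' @slot mask logical 3D array.
#' @slot stage one of "raw", "normalized", "smoothed".
#' @slot affine 4 x 4 voxel-to-mm transform.
#' @slot subjectID subject identifier.
#'
#' @seealso [rehoMap()], [normalizeGlobalMean()], [smoothGaussian()]
#' @export
setClass("ReHoMap",
    representation(values = "array", mask = "array", stage = "character",
                   affine = "matrix", subjectID = "character"))

setValidity("ReHoMap", function(object) {
    if (length(dim(object@values)) != 3L)
        return("'values' must be a 3D array")
    if (!identical(dim(object@values), dim(object@mask)))
        return("'mask' dimensions must match 'values'")
    if (!is.logical(object@mask))
        return("'mask' must be a logical array")
    if (!object@stage %in% c("raw", "normalized", "smoothed"))
        return("'stage' must be raw, normalized or smoothed")
    inm <- object@values[object@mask]
    if (object@stage == "raw" &&
        length(inm) && (min(inm) < -1e-12 || max(inm) > 1 + 1e-12))
        return("raw-stage values must lie in [0, 1] inside the mask")
    if (object@stage == "normalized" && length(inm) &&
        abs(mean(inm) - 1) > 1e-10)
        return("normalized-stage in-mask mean must equal 1")
    if (any(object@values[!object@mask] != 0))
        return("values outside the mask must be 0")
    TRUE
})

#' Subject-by-voxel feature matrix
#'
#' Vectorized in-mask voxel values for a set of subjects, with the
#' column-to-grid-coordinate mapping retained so weight vectors can be
#' projected back into volume space. Columns are ordered
#' lexicographically by (i, j, k) grid coordinate.
#'
#' @slot values subjects x voxels matrix.
#' @slot voxelIndex voxels x 3 integer matrix of grid coordinates
#'   (1-based).
#' @slot gridDim integer 3-vector, the spatial grid.
#' @slot subjectIDs row identifiers.
#' @slot affine 4 x 4 voxel-to-mm transform.
#'
#' @seealso [buildFeatures()], [weightsToMap()]
#' @export
setClass("FeatureMatrix",
    representation(values = "matrix", voxelIndex = "matrix",
                   gridDim = "integer", subjectIDs = "character",
                   affine = "matrix"))

setValidity("FeatureMatrix", function(object) {
    if (ncol(object@values) != nrow(object@voxelIndex))
        return("column count must equal voxelIndex row count")
    if (nrow(object@values) != length(object@subjectIDs))
        return("row count must equal subjectIDs length")
    if (ncol(object@voxelIndex) != 3L)
        return("'voxelIndex' must have 3 columns")
    TRUE
})

#' Fitted linear decision model
#'
#' A linear classifier f(x) = w0 + w'x in voxel-feature space. For the
#' Gaussian-process classifiers the weights are the kernel-space dual
#' coefficients pulled back to feature space; one column per class for
#' the multiclass model, a single positive-class-oriented column for
#' binary models.
#'
#' @slot weights features x classes (or x 1) weight matrix.
#' @slot bias per-column intercepts w0.
#' @slot classes class labels; for binary models the first element is
#'   the positive class.
#' @slot algorithm "svm", "bgpc" or "mgpc".
#' @slot fit algorithm-specific details (dual coefficients, iterations).
#'
#' @seealso [fitLinearSVM()], [fitGPC()]
#' @export
setClass("LinearModel",
    representation(weights = "matrix", bias = "numeric",
                   classes = "character", algorithm = "character",
                   fit = "list"))

#' Leave-one-subject-out cross-validation result
#'
#' Per-subject held-out predictions and decision scores, the assembled
#' confusion matrix, derived performance metrics, and the per-fold
#' weight vectors used for discriminative mapping.
#'
#' @slot predicted held-out predicted label per subject.
#' @slot scores held-out decision scores (positive-class oriented for
#'   binary models; class-probability matrix columns for multiclass).
#' @slot labels true labels.
#' @slot confusion confusion matrix, rows = truth, columns = predicted.
#' @slot metrics list of performance metrics (proportions in \[0, 1\]).
#' @slot foldWeights folds x features matrix of positive-class-oriented
#'   weights (binary algorithms; empty for multiclass).
#' @slot foldBias per-fold intercepts.
#' @slot classes class labels (binary: positive class first).
#' @slot algorithm classifier used.
#'
#' @seealso [losocv()], [performanceMetrics()]
#' @export
setClass("CVResult",
    representation(predicted = "character", scores = "matrix",
                   labels = "character", confusion = "matrix",
                   metrics = "list", foldWeights = "matrix",
                   foldBias = "numeric", classes = "character",
                   algorithm = "character"))

setValidity("CVResult", function(object) {
    n <- length(object@labels)
    if (length(object@predicted) != n)
        return("one prediction per subject is required")
    if (sum(object@confusion) != n)
        return("confusion matrix entries must sum to the subject count")
    TRUE
})

#' Label-permutation significance result
#'
#' Null distributions of classification performance metrics (and
#' optionally of voxel weights) obtained by re-running the full
#' leave-one-subject-out procedure under uniformly permuted labels.
#' p = count(null >= observed) / nPerm; a count of zero is displayed as
#' "p < 1/nPerm".
#'
#' @slot observed observed metric values.
#' @slot nullValues nPerm x metrics matrix of permuted values.
#' @slot pValues per-metric permutation p-values.
#' @slot nPerm,seed permutation count and RNG seed.
#' @slot observedWeights mean observed weight per voxel (may be empty).
#' @slot nullWeights nPerm x voxels matrix (may be empty).
#'
#' @seealso [permutePerformance()], [permuteVoxelWeights()]
#' @export
setClass("PermutationResult",
    representation(observed = "numeric", nullValues = "matrix",
                   pValues = "numeric", nPerm = "integer",
                   seed = "integer", observedWeights = "numeric",
                   nullWeights = "matrix"))

setValidity("PermutationResult", function(object) {
    if (length(object@pValues) &&
        (min(object@pValues) < 0 || max(object@pValues) > 1))
        return("p-values must lie in [0, 1]")
    TRUE
})

#' Suprathreshold discriminative cluster
#'
#' A connected component of voxels whose permutation p-values pass the
#' voxel threshold, larger than the extent cutoff; signed by the mean
#' classifier weight over its voxels.
#'
#' @slot voxels n x 3 integer matrix of grid coordinates.
#' @slot peak grid coordinate of the largest-|w| voxel.
#' @slot sign "positive" or "negative".
#' @slot label cluster label.
#'
#' @seealso [extractClusters()]
#' @export
setClass("ClusterROI",
    representation(voxels = "matrix", peak = "integer", sign = "character",
                   label = "character"))

#' Discriminative weight map with permutation inference
#'
#' The across-fold mean classifier weight map, per-voxel permutation
#' p-values, and the clusters surviving the voxel threshold and the
#' extent cutoff (the ROIs of the analysis).
#'
#' @slot meanWeight signed 3D weight map.
#' @slot voxelP 3D map of per-voxel permutation p-values.
#' @slot mask logical 3D analysis mask.
#' @slot clusters list of [ClusterROI-class] objects.
#' @slot alpha voxel p threshold.
#' @slot minClusterVoxels extent cutoff (strictly-greater-than rule).
#' @slot nPerm permutations behind voxelP.
#' @slot affine 4 x 4 voxel-to-mm transform.
#'
#' @seealso [discriminativeMap()], [extractClusters()]
#' @export
setClass("DiscriminativeMap",
    representation(meanWeight = "array", voxelP = "array", mask = "array",
                   clusters = "list", alpha = "numeric",
                   minClusterVoxels = "integer", nPerm = "integer",
                   affine = "matrix"))

setValidity("DiscriminativeMap", function(object) {
    for (cl in object@clusters) {
        if (nrow(cl@voxels) <= object@minClusterVoxels)
            return("every cluster must exceed minClusterVoxels voxels")
        pv <- object@voxelP[cl@voxels]
        if (any(pv >= object@alpha))
            return("clusters may contain only voxels with p < alpha")
    }
    TRUE
})

#' Lazily materialized synthetic cohort
#'
#' Subject records, per-region coherence perturbations and per-subject
#' RNG seeds for a simulated three-group cohort. Volumes are generated
#' on demand with [subjectSeries()] so that large cohorts never need to
#' be held in memory at once.
#'
#' @slot config validated configuration list (see [syntheticConfig()]).
#' @slot records subject table (one row per subject).
#' @slot delta subjects x effect-regions matrix of coherence
#'   perturbations.
#' @slot seeds per-subject integer seeds.
#' @slot mask logical 3D analysis mask.
#'
#' @seealso [syntheticCohort()], [generateCohort()]
#' @export
setClass("SyntheticCohort",
    representation(config = "list", records = "data.frame",
                   delta = "matrix", seeds = "integer", mask = "array"))
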