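#' @importFrom stats rnorm runif rbinom
NULL

# Cohort moments used to calibrate the clinical-covariate simulator:
# per-group means/SDs of the demographic and clinical scales, and the
# male fraction. Tremor scales are undefined for healthy controls (NA).
.clinicalMoments <- list(
    DET = list(age = c(47.85, 15.66), education = c(14.73, 4.17),
               mmse = c(26.00, 1.40), hars14 = c(7.56, 3.47),
               hdrs17 = c(18.98, 6.35), trs_ab = c(22.66, 7.28),
               trs_c = c(14.05, 4.74), tetras = c(18.32, 8.27),
               maleFrac = 26 / 41, hdrsFloor = 7),
    ET  = list(age = c(44.49, 13.73), education = c(12.40, 3.77),
               mmse = c(26.33, 1.51), hars14 = c(4.09, 1.66),
               hdrs17 = c(3.49, 1.56), trs_ab = c(20.93, 7.77),
               trs_c = c(10.70, 5.22), tetras = c(17.41, 6.79),
               maleFrac = 28 / 43, hdrsFloor = 0),
    HC  = list(age = c(46.67, 13.16), education = c(12.22, 3.42),
               mmse = c(28.67, 1.35), hars14 = c(2.04, 1.17),
               hdrs17 = c(2.11, 1.17), trs_ab = c(NA, NA),
               trs_c = c(NA, NA), tetras = c(NA, NA),
               maleFrac = 28 / 45, hdrsFloor = 0))

.groupLevels <- c("DET", "ET", "HC")

#' Define an effect region for the synthetic cohort
#'
#' An axis-aligned box of voxels inside which every subject's time
#' series is a mixture of a shared regional time course and private
#' noise: series = sqrt(c) * shared + sqrt(1 - c) * private, where c is
#' the group's coherence (plus a per-subject perturbation). Kendall's W
#' over the box rises monotonically with c; c = 0 leaves pure
#' independent noise.
#'
#' @param boxMin,boxMax integer 3-vectors, inclusive corners of the box
#'   in 1-based grid coordinates.
#' @param coherenceByGroup numeric 3-vector in \[0, 1\]: mixing weight
#'   for the DET, ET and HC groups (in that order).
#' @param hdrsCoupling slope linking a subject's coherence perturbation
#'   in this region to their simulated HDRS-17 score; positive values
#'   make locally *more* coherent DET subjects more depressed.
#' @return an object of class `EffectRegion` (a validated list).
#' @examples
#' effectRegion(c(5, 5, 5), c(10, 10, 10), c(0.8, 0.4, 0.1))
#' @export
effectRegion <- function(boxMin, boxMax, coherenceByGroup,
                         hdrsCoupling = 0) {
    boxMin <- as.integer(boxMin); boxMax <- as.integer(boxMax)
    if (length(boxMin) != 3L || length(boxMax) != 3L)
        stop("effectRegion: 'boxMin'/'boxMax' must be 3-vectors")
    if (any(boxMax < boxMin))
        stop("effectRegion: 'boxMax' must be >= 'boxMin' on every axis")
    if (length(coherenceByGroup) != 3L ||
        any(coherenceByGroup < 0) || any(coherenceByGroup > 1))
        stop("effectRegion: 'coherenceByGroup' must be 3 values in [0, 1]")
    structure(list(boxMin = boxMin, boxMax = boxMax,
                   coherenceByGroup = as.numeric(coherenceByGroup),
                   hdrsCoupling = as.numeric(hdrsCoupling)),
              class = "EffectRegion")
}

#' Configuration for the synthetic three-group cohort
#'
#' Defaults mirror the study conditions the simulator emulates: three
#' groups of 41/43/45 subjects (depressed tremor patients, non-depressed
#' tremor patients, healthy controls), 230 retained volumes at TR = 2 s,
#' a 24^3 grid of 3 mm voxels, and temporally autocorrelated baseline
#' noise.
#'
#' @param gridShape integer 3-vector of voxels per axis (each >= 3).
#' @param nTimepoints number of volumes (>= 20).
#' @param trSeconds repetition time in seconds.
#' @param groupSizes named or ordered 3-vector: DET, ET, HC counts.
#' @param effectRegions list of [effectRegion()] objects.
#' @param noiseAR1 lag-1 autocorrelation of the baseline noise, in
#'   \[0, 1).
#' @param coherenceSD SD of the per-subject, per-region coherence
#'   perturbation feeding the HDRS-17 coupling.
#' @param seed integer RNG seed fixing every voxel and covariate.
#' @param highMotion 3-vector: number of subjects per group to inject
#'   with high head motion (mean FDpower above the 0.2 mm gate);
#'   defaults to none, so all subjects pass the gate.
#' @param voxelSizeMM voxel edge lengths in mm.
#' @return a validated configuration list of class `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig(gridShape = c(8, 8, 8), nTimepoints = 40,
#'                        groupSizes = c(3, 3, 3), seed = 7)
#' @export
syntheticConfig <- function(gridShape = c(24L, 24L, 24L),
                            nTimepoints = 230L, trSeconds = 2,
                            groupSizes = c(DET = 41L, ET = 43L, HC = 45L),
                            effectRegions = list(), noiseAR1 = 0.3,
                            coherenceSD = 0.05, seed = 1L,
                            highMotion = c(0L, 0L, 0L),
                            voxelSizeMM = c(3, 3, 3)) {
    cfg <- list(gridShape = as.integer(gridShape),
                nTimepoints = as.integer(nTimepoints),
                trSeconds = as.numeric(trSeconds),
                groupSizes = as.integer(groupSizes),
                effectRegions = effectRegions,
                noiseAR1 = as.numeric(noiseAR1),
                coherenceSD = as.numeric(coherenceSD),
                seed = as.integer(seed),
                highMotion = as.integer(highMotion),
                voxelSizeMM = as.numeric(voxelSizeMM))
    class(cfg) <- "SyntheticConfig"
    validateSyntheticConfig(cfg)
    cfg
}

validateSyntheticConfig <- function(cfg) {
    if (length(cfg$gridShape) != 3L || any(cfg$gridShape < 3L))
        stop("syntheticConfig: 'gridShape' needs 3 axes of >= 3 voxels ",
             "(27-voxel neighborhoods must exist)")
    if (cfg$nTimepoints < 20L)
        stop("syntheticConfig: 'nTimepoints' must be >= 20")
    if (cfg$trSeconds <= 0)
        stop("syntheticConfig: 'trSeconds' must be positive")
    if (length(cfg$groupSizes) != 3L || any(cfg$groupSizes < 0L))
        stop("syntheticConfig: 'groupSizes' must be 3 non-negative counts")
    if (cfg$noiseAR1 < 0 || cfg$noiseAR1 >= 1)
        stop("syntheticConfig: 'noiseAR1' must lie in [0, 1)")
    if (length(cfg$highMotion) != 3L || any(cfg$highMotion < 0L) ||
        any(cfg$highMotion > cfg$groupSizes))
        stop("syntheticConfig: 'highMotion' must give per-group counts ",
             "no larger than 'groupSizes'")
    for (r in cfg$effectRegions) {
        if (!inherits(r, "EffectRegion"))
            stop("syntheticConfig: 'effectRegions' must be a list of ",
                 "effectRegion() objects")
        if (any(r$boxMin < 1L) || any(r$boxMax > cfg$gridShape))
            stop("syntheticConfig: 'effectRegions' box exceeds 'gridShape'")
    }
    invisible(cfg)
}

#' Simulate clinical and demographic records for one group
#'
#' Draws covariates from independent normals with the per-group cohort
#' means and SDs; HDRS-17 uses a lower-truncated normal whose location
#' is solved so the truncated mean equals the target mean (depressed
#' subjects always score >= 7). Tremor scales are NA for healthy
#' controls. Mean FDpower is uniform on \[0.05, 0.18\] mm, below the
#' 0.2 mm exclusion gate.
#'
#' @param group "DET", "ET" or "HC".
#' @param n number of subjects (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with one row per subject.
#' @examples
#' generateClinical("DET", 5, seed = 1)
#' @export
generateClinical <- function(group, n, seed) {
    if (!group %in% .groupLevels)
        stop("generateClinical: unknown group label '", group, "'")
    if (n < 0) stop("generateClinical: 'n' must be >= 0")
    set.seed(as.integer(seed))
    .drawClinical(group, n, delta = NULL, couplings = NULL,
                  idPrefix = group)
}

# Core covariate draw; `delta` (n x R) and `couplings` (length R) add
# the coherence-perturbation term to HDRS-17 before flooring.
.drawClinical <- function(group, n, delta, couplings, idPrefix) {
    mo <- .clinicalMoments[[group]]
    drawPos <- function(m) {
        if (is.na(m[1])) return(rep(NA_real_, n))
        rtruncnormLower(n, matchTruncnormMean(m[1], m[2], 0), m[2], 0)
    }
    floorH <- mo$hdrsFloor
    muH <- matchTruncnormMean(mo$hdrs17[1], mo$hdrs17[2], floorH)
    hdrs <- rtruncnormLower(n, muH, mo$hdrs17[2], floorH)
    if (!is.null(delta) && length(couplings))
        hdrs <- pmax(hdrs + drop(delta %*% couplings), floorH)
    out <- data.frame(
        subject_id = if (n) sprintf("%s%03d", idPrefix, seq_len(n))
                     else character(0),
        group = rep(group, n),
        hdrs17 = hdrs,
        hars14 = drawPos(mo$hars14),
        mmse = drawPos(mo$mmse),
        trs_ab = drawPos(mo$trs_ab),
        trs_c = drawPos(mo$trs_c),
        tetras = drawPos(mo$tetras),
        age = drawPos(mo$age),
        education = drawPos(mo$education),
        sex = if (n) rbinom(n, 1L, mo$maleFrac) else integer(0),
        fd_power = runif(n, 0.05, 0.18),
        stringsAsFactors = FALSE)
    out
}

#' Create a lazily materialized synthetic cohort
#'
#' Draws all subject records, per-region coherence perturbations and
#' per-subject volume seeds under the configuration seed. Volumes are
#' generated on demand by [subjectSeries()]; [generateCohort()]
#' materializes everything at once.
#'
#' @param config a [syntheticConfig()] object.
#' @return a [SyntheticCohort-class] object.
#' @examples
#' co <- syntheticCohort(syntheticConfig(gridShape = c(6, 6, 6),
#'                       nTimepoints = 30, groupSizes = c(2, 2, 2)))
#' cohortRecords(co)$group
#' @export
syntheticCohort <- function(config) {
    validateSyntheticConfig(config)
    set.seed(config$seed)
    nR <- length(config$effectRegions)
    couplings <- vapply(config$effectRegions,
                        function(r) r$hdrsCoupling, numeric(1))
    recs <- list(); deltas <- list()
    for (gi in seq_along(.groupLevels)) {
        g <- .groupLevels[gi]
        n <- config$groupSizes[gi]
        d <- matrix(rnorm(n * nR, 0, config$coherenceSD), n, nR)
        recs[[g]] <- .drawClinical(g, n, d, couplings, g)
        # high-motion injection: last k subjects of the group
        k <- config$highMotion[gi]
        if (k > 0 && n > 0) {
            idx <- seq.int(n - k + 1L, n)
            recs[[g]]$fd_power[idx] <- runif(k, 0.21, 0.35)
        }
        deltas[[g]] <- d
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    seeds <- deriveSeeds(config$seed, nrow(records) + 1L)[-1L]
    mask <- array(TRUE, dim = config$gridShape)
    new("SyntheticCohort", config = unclass(config), records = records,
        delta = do.call(rbind, deltas), seeds = seeds, mask = mask)
}

#' Materialize one subject's BOLD-like volume
#'
#' Baseline AR(1) noise everywhere; inside each effect region the series
#' is sqrt(c) * shared regional AR(1) course + sqrt(1 - c) * the private
#' baseline noise, with c the subject's (group coherence + perturbation)
#' clamped to \[0, 1\]. Deterministic given the cohort seed.
#'
#' @param cohort a [SyntheticCohort-class] object.
#' @param i subject index (row of the record table).
#' @return a [BoldSeries-class] object.
#' @export
subjectSeries <- function(cohort, i) {
    cfg <- cohort@config
    rec <- cohort@records[i, ]
    set.seed(cohort@seeds[i])
    d <- cfg$gridShape
    tt <- cfg$nTimepoints
    phi <- cfg$noiseAR1
    nvox <- prod(d)
    base <- ar1Matrix(tt, nvox, phi)              # T x V unit-variance
    gi <- match(rec$group, .groupLevels)
    for (ri in seq_along(cfg$effectRegions)) {
        r <- cfg$effectRegions[[ri]]
        csub <- min(max(r$coherenceByGroup[gi] + cohort@delta[i, ri], 0), 1)
        shared <- drop(ar1Matrix(tt, 1L, phi))
        sel <- boxLinearIndex(r$boxMin, r$boxMax, d)
        base[, sel] <- sqrt(csub) * shared +
            sqrt(1 - csub) * base[, sel]
    }
    arr <- array(t(base), dim = c(d, tt))
    new("BoldSeries", data = arr, trSeconds = cfg$trSeconds,
        affine = identityAffine(cfg$voxelSizeMM),
        subjectID = rec$subject_id)
}

# T x V matrix of unit-variance AR(1) series (burn-in discarded).
ar1Matrix <- function(tt, v, phi) {
    burn <- 50L
    e <- matrix(rnorm((tt + burn) * v), tt + burn, v)
    if (phi > 0) {
        x <- stats::filter(e, phi, method = "recursive")
        x <- x * sqrt(1 - phi^2)
    } else x <- e
    matrix(x[burn + seq_len(tt), ], tt, v)
}

boxLinearIndex <- function(boxMin, boxMax, gridDim) {
    co <- as.matrix(expand.grid(seq.int(boxMin[1], boxMax[1]),
                                seq.int(boxMin[2], boxMax[2]),
                                seq.int(boxMin[3], boxMax[3])))
    co[, 1] + (co[, 2] - 1L) * gridDim[1] +
        (co[, 3] - 1L) * gridDim[1] * gridDim[2]
}

#' Generate a full synthetic cohort in memory
#'
#' Convenience wrapper around [syntheticCohort()] + [subjectSeries()].
#' For large grids or cohorts prefer the lazy interface (one 24^3 x 230
#' volume is ~25 MB).
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `series` (list of [BoldSeries-class]),
#'   `records` (data.frame), `mask` (logical array) and `cohort` (the
#'   lazy object).
#' @export
generateCohort <- function(config) {
    co <- syntheticCohort(config)
    series <- lapply(seq_len(nrow(co@records)),
                     function(i) subjectSeries(co, i))
    list(series = series, records = co@records, mask = co@mask,
         cohort = co)
}

#' @describeIn syntheticCohort subject record accessor
#' @param cohort a [SyntheticCohort-class] object.
#' @export
cohortRecords <- function(cohort) cohort@records

#' @describeIn syntheticCohort analysis mask accessor
#' @export
cohortMask <- function(cohort) cohort@mask

#' Write a synthetic cohort to disk
#'
#' One gzipped 4D NIfTI per subject, one 3D mask NIfTI, the record table
#' as CSV, and the configuration as a key:value text file.
#'
#' @param cohort a [SyntheticCohort-class] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- cohort@config
    paths <- character(0)
    for (i in seq_len(nrow(cohort@records))) {
        s <- subjectSeries(cohort, i)
        p <- file.path(dir, paste0(s@subjectID, "_bold.nii.gz"))
        writeVolume(s, p)
        paths <- c(paths, p)
    }
    maskPath <- file.path(dir, "mask.nii.gz")
    writeMaskVolume(cohort@mask, identityAffine(cfg$voxelSizeMM), maskPath)
    recPath <- file.path(dir, "cohort.csv")
    writeCohortTable(cohort@records, recPath)
    cfgPath <- file.path(dir, "config.yaml")
    writeConfigFile(cfg, cfgPath)
    invisible(c(paths, maskPath, recPath, cfgPath))
}
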