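#' @importFrom RNifti readNifti writeNifti asNifti niftiHeader pixdim
#' @importFrom RNifti xform sform qform
#' @importFrom RNifti "pixdim<-" "qform<-" "sform<-"
NULL

#' Write a BOLD series or ReHo map as NIfTI-1
#'
#' 4D series carry the repetition time in the NIfTI time pixdim; maps
#' record their processing stage in the header description field.
#' Gzipped output is selected by the ".nii.gz" extension.
#'
#' @param x a [BoldSeries-class] or [ReHoMap-class] object.
#' @param path output file (.nii or .nii.gz).
#' @return invisibly, `path`.
#' @export
writeVolume <- function(x, path) {
    if (is(x, "BoldSeries")) {
        img <- asNifti(x@data)
        pixdim(img) <- c(voxelSizes(x@affine), x@trSeconds)
        RNifti::qform(img) <- structure(x@affine, code = 2L)
        img$descrip <- paste0("bold;subject=", x@subjectID)
    } else if (is(x, "ReHoMap")) {
        img <- asNifti(x@values)
        pixdim(img) <- voxelSizes(x@affine)
        RNifti::qform(img) <- structure(x@affine, code = 2L)
        img$descrip <- paste0("stage=", x@stage, ";subject=", x@subjectID)
    } else stop("writeVolume: unsupported object of class ", class(x))
    writeNifti(img, path)
    invisible(path)
}

# Arbitrary 3D statistic map (signed weights, p-values, ...).
writeStatVolume <- function(values, affine, path, descrip = "stat") {
    img <- asNifti(values)
    pixdim(img) <- voxelSizes(affine)
    RNifti::qform(img) <- structure(affine, code = 2L)
    img$descrip <- descrip
    writeNifti(img, path)
    invisible(path)
}

writeMaskVolume <- function(mask, affine, path) {
    img <- asNifti(array(as.integer(mask), dim = dim(mask)))
    pixdim(img) <- voxelSizes(affine)
    RNifti::qform(img) <- structure(affine, code = 2L)
    img$descrip <- "mask"
    writeNifti(img, path)
    invisible(path)
}

parseDescrip <- function(descrip) {
    parts <- strsplit(descrip, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    out <- list()
    for (p in kv) if (length(p) == 2L) out[[p[1]]] <- p[2]
    out
}

#' Read a NIfTI volume written by this package
#'
#' 4D files come back as [BoldSeries-class] (TR from the time pixdim);
#' 3D files as [ReHoMap-class] with the stage restored from the header
#' description (stage "raw" and an all-TRUE mask if absent). Non-finite
#' voxels are an error.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param mask optional logical array for 3D maps.
#' @return a [BoldSeries-class] or [ReHoMap-class] object.
#' @export
readVolume <- function(path, mask = NULL) {
    img <- readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    if (!all(is.finite(arr)))
        stop("readVolume: non-finite values in ", path)
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = dim(aff))
    meta <- parseDescrip(niftiHeader(img)$descrip)
    sid <- meta$subject %||% sub("\\.nii(\\.gz)?$", "", basename(path))
    if (length(dim(arr)) == 4L) {
        tr <- pixdim(img)[4]
        new("BoldSeries", data = arr, trSeconds = tr, affine = aff,
            subjectID = sid)
    } else if (length(dim(arr)) == 3L) {
        stage <- meta$stage %||% "raw"
        if (is.null(mask)) {
            # without an explicit mask, take nonzero voxels for the
            # normalized stage (whose class invariant is mask-relative)
            mask <- if (stage == "normalized")
                array(arr != 0, dim = dim(arr))
            else array(TRUE, dim = dim(arr))
        }
        vals <- arr
        vals[!mask] <- 0
        new("ReHoMap", values = vals, mask = mask, stage = stage,
            affine = aff, subjectID = sid)
    } else stop("readVolume: expected a 3D or 4D volume in ", path)
}

readMaskVolume <- function(path) {
    img <- readNifti(path)
    array(as.numeric(img) != 0, dim = dim(img))
}

#' Read and write the subject record table
#'
#' Comma-separated text with a header row. Reading validates that the
#' mandatory columns (`subject_id`, `group`) are present.
#'
#' @param records data.frame of subject records.
#' @param path CSV file path.
#' @return `readCohortTable`: the data.frame; `writeCohortTable`:
#'   invisibly, `path`.
#' @export
writeCohortTable <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (col in c("subject_id", "group"))
        if (!col %in% names(tab))
            stop("readCohortTable: required column '", col,
                 "' is missing from ", path)
    tab
}

#' Read and write motion-parameter text files
#'
#' Six-column whitespace-delimited text, one row per volume (the
#' realignment-parameter convention).
#'
#' @param motion6 T x 6 matrix.
#' @param path text file path.
#' @return `readMotionParams`: T x 6 matrix.
#' @export
writeMotionParams <- function(motion6, path) {
    utils::write.table(motion6, path, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname writeMotionParams
#' @export
readMotionParams <- function(path) {
    m <- as.matrix(utils::read.table(path))
    if (ncol(m) != 6L)
        stop("readMotionParams: expected 6 columns in ", path)
    dimnames(m) <- NULL
    m
}

# ---- pipeline configuration ------------------------------------------

.pipelineDefaults <- function() list(
    input_dir = NULL,
    output_dir = "reho-mvpa-output",
    # synthetic-cohort parameters (used when input_dir is NULL)
    grid_shape = c(24L, 24L, 24L),
    n_timepoints = 230L,
    tr_seconds = 2,
    group_sizes = c(41L, 43L, 45L),
    noise_ar1 = 0.3,
    coherence_sd = 0.05,
    high_motion = c(0L, 0L, 0L),
    effect_regions = list(),
    voxel_size_mm = c(3, 3, 3),
    # stage parameters
    fd_threshold_mm = 0.2,
    low_hz = 0.01,
    high_hz = 0.08,
    fwhm_mm = 4,
    algorithm = "svm",
    c_param = 1,
    n_perm = 1000L,
    alpha = 0.001,
    min_cluster = 30L,
    connectivity = 26L,
    positive_class = "DET",
    correlation_alpha = 0.05,
    bonferroni_mode = "tests",
    seed = 1L)

#' Assemble and validate a pipeline configuration
#'
#' Named arguments override the defaults; unknown keys are rejected.
#' When `input_dir` is NULL the synthetic cohort defined by the
#' `grid_shape`/`group_sizes`/`effect_regions` keys is simulated;
#' otherwise volumes, mask and records are read from `input_dir` (the
#' layout written by [writeCohort()]).
#'
#' @param ... configuration keys to override.
#' @return validated configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
    cfg <- .pipelineDefaults()
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("pipelineConfig: unknown key(s): ",
             paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    # effect regions read back from a config file arrive as plain
    # lists; rebuild (and thereby re-validate) them
    cfg$effect_regions <- lapply(cfg$effect_regions, function(r) {
        if (inherits(r, "EffectRegion")) r
        else effectRegion(r$boxMin, r$boxMax, r$coherenceByGroup,
                          r$hdrsCoupling %||% 0)
    })
    if (cfg$n_perm < 0L) stop("pipelineConfig: 'n_perm' must be >= 0")
    if (cfg$alpha <= 0 || cfg$alpha > 1)
        stop("pipelineConfig: 'alpha' must lie in (0, 1]")
    if (!cfg$connectivity %in% c(6L, 18L, 26L))
        stop("pipelineConfig: 'connectivity' must be 6, 18 or 26")
    if (!cfg$algorithm %in% c("svm", "bgpc"))
        stop("pipelineConfig: binary 'algorithm' must be svm or bgpc")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read and write a pipeline or cohort configuration file
#'
#' Structured key: value text (YAML subset).
#'
#' @param cfg configuration list.
#' @param path file path.
#' @return `readConfigFile`: the configuration list.
#' @export
writeConfigFile <- function(cfg, path) {
    plain <- unclass(cfg)
    for (key in c("effectRegions", "effect_regions"))
        if (!is.null(plain[[key]]))
            plain[[key]] <- lapply(plain[[key]], unclass)
    yaml::write_yaml(plain, path)
    invisible(path)
}

#' @rdname writeConfigFile
#' @export
readConfigFile <- function(path) {
    yaml::read_yaml(path)
}
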