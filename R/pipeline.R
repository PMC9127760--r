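#' Run the full analysis workflow
#'
#' Orchestrates the complete chain on a cohort: head-motion exclusion,
#' temporal preprocessing (nuisance regression where motion files are
#' available, detrending, band-pass), voxelwise ReHo with global-mean
#' normalization and Gaussian smoothing, leave-one-subject-out
#' classification of the three binary contrasts (DET vs HC, ET vs HC,
#' DET vs ET) and the three-class problem, permutation inference with
#' cluster-extent thresholding for the positive-class-vs-control
#' contrast, and covariate-adjusted ROI-severity partial correlation.
#' All artifacts are written under `output_dir` together with a
#' manifest (input checksums, parameters, seed, package version);
#' reruns with an identical configuration reproduce every output.
#'
#' @param config a [pipelineConfig()] object.
#' @param verbose emit one key=value progress line per stage to stderr.
#' @return invisibly, a run report list: retained records, per-contrast
#'   [CVResult-class]s, the [PermutationResult-class] and
#'   [DiscriminativeMap-class] (when `n_perm > 0`), the ROI correlation
#'   table, and output paths.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    if (!inherits(config, "PipelineConfig"))
        stop("runPipeline: 'config' must come from pipelineConfig()")
    say <- function(...) if (verbose)
        message(sprintf("stage=%s", sprintf(...)))
    outDir <- config$output_dir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    # ---- cohort -------------------------------------------------------
    inputChecksums <- character(0)
    if (is.null(config$input_dir)) {
        scfg <- syntheticConfig(gridShape = config$grid_shape,
                                nTimepoints = config$n_timepoints,
                                trSeconds = config$tr_seconds,
                                groupSizes = config$group_sizes,
                                effectRegions = config$effect_regions,
                                noiseAR1 = config$noise_ar1,
                                coherenceSD = config$coherence_sd,
                                seed = config$seed,
                                highMotion = config$high_motion,
                                voxelSizeMM = config$voxel_size_mm)
        cohort <- syntheticCohort(scfg)
        records <- cohort@records
        mask <- cohort@mask
        affine <- identityAffine(config$voxel_size_mm)
        loadSeries <- function(i) subjectSeries(cohort, i)
        motionFor <- function(rec) NULL
        say("simulate subjects=%d", nrow(records))
    } else {
        records <- readCohortTable(file.path(config$input_dir,
                                             "cohort.csv"))
        maskPath <- file.path(config$input_dir, "mask.nii.gz")
        if (!file.exists(maskPath))
            maskPath <- file.path(config$input_dir, "mask.nii")
        mask <- readMaskVolume(maskPath)
        boldPaths <- file.path(config$input_dir,
                               paste0(records$subject_id, "_bold.nii.gz"))
        missing <- boldPaths[!file.exists(boldPaths)]
        if (length(missing))
            stop("runPipeline: missing volume files: ",
                 paste(missing, collapse = ", "))
        inputChecksums <- tools::md5sum(c(boldPaths, maskPath))
        affine <- NULL
        loadSeries <- function(i) readVolume(boldPaths[i])
        motionFor <- function(rec) {
            p <- file.path(config$input_dir,
                           paste0(rec$subject_id, "_motion.txt"))
            if (file.exists(p)) readMotionParams(p) else NULL
        }
        say("load subjects=%d", nrow(records))
    }

    # ---- head-motion gate --------------------------------------------
    excl <- excludeByMotion(records, config$fd_threshold_mm)
    retained <- excl$retained
    utils::write.csv(excl$report, file.path(outDir, "exclusion.csv"),
                     row.names = FALSE)
    say("exclude retained=%d excluded=%d", nrow(retained),
        length(excl$excluded))
    if (nrow(retained) < 3L)
        stop("runPipeline: fewer than 3 subjects retained after the ",
             "motion gate")

    # ---- preprocessing + ReHo per subject ----------------------------
    keepIdx <- match(retained$subject_id, records$subject_id)
    maps <- vector("list", length(keepIdx))
    for (j in seq_along(keepIdx)) {
        i <- keepIdx[j]
        s <- tryCatch({
            ser <- loadSeries(i)
            m6 <- motionFor(records[i, ])
            conf <- if (is.null(m6)) NULL else {
                y <- seriesMatrix(ser)
                confoundSet(motion6 = m6, global = rowMeans(y))
            }
            ser <- preprocessBold(ser, conf, config$low_hz,
                                  config$high_hz)
            smReHo(ser, mask, config$fwhm_mm)
        }, error = function(e)
            stop("runPipeline: stage=reho subject=",
                 records$subject_id[i], ": ", conditionMessage(e)))
        if (is.null(affine)) affine <- s@affine
        maps[[j]] <- s
        writeVolume(s, file.path(outDir,
                    paste0(retained$subject_id[j], "_smreho.nii.gz")))
    }
    say("reho maps=%d", length(maps))

    # ---- classification ----------------------------------------------
    features <- buildFeatures(maps, mask)
    contrasts <- list(DET_vs_HC = c("DET", "HC"),
                      ET_vs_HC = c("ET", "HC"),
                      DET_vs_ET = c("DET", "ET"))
    cvs <- list(); metricsRows <- list()
    for (nm in names(contrasts)) {
        gs <- contrasts[[nm]]
        sel <- retained$group %in% gs
        if (sum(retained$group[sel] == gs[1]) < 2L ||
            sum(retained$group[sel] == gs[2]) < 2L) next
        pos <- if (config$positive_class %in% gs) config$positive_class
               else gs[1]
        cv <- losocv(features@values[sel, , drop = FALSE],
                     retained$group[sel], config$algorithm,
                     positiveClass = pos, cParam = config$c_param)
        cvs[[nm]] <- cv
        metricsRows[[nm]] <- data.frame(
            task = nm, algorithm = config$algorithm,
            positive_class = pos,
            t(unlist(cv@metrics[c("total_accuracy", "balanced_accuracy",
                                  "sensitivity", "specificity", "ppv",
                                  "npv", "auc")])))
        writeConfusion(cv, file.path(outDir,
                       paste0("confusion_", nm, ".txt")))
        roc <- rocCoordinates(cv@scores[, 1L],
                              cv@labels, pos)
        utils::write.table(roc[, c("fpr", "tpr")],
                           file.path(outDir, paste0("roc_", nm, ".txt")),
                           row.names = FALSE, col.names = FALSE)
        say("classify task=%s accuracy=%.4f", nm,
            cv@metrics$total_accuracy)
    }
    if (length(unique(retained$group)) >= 3L) {
        cv3 <- losocv(features, retained$group, "mgpc")
        cvs[["three_class"]] <- cv3
        metricsRows[["three_class"]] <- data.frame(
            task = "three_class", algorithm = "mgpc",
            positive_class = NA,
            total_accuracy = cv3@metrics$total_accuracy,
            balanced_accuracy = cv3@metrics$balanced_accuracy,
            sensitivity = NA, specificity = NA, ppv = NA, npv = NA,
            auc = NA)
        writeConfusion(cv3, file.path(outDir, "confusion_three_class.txt"))
        say("classify task=three_class accuracy=%.4f",
            cv3@metrics$total_accuracy)
    }
    metricsTab <- do.call(rbind, c(metricsRows,
                                   list(make.row.names = FALSE)))
    utils::write.csv(metricsTab, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)

    # ---- permutation inference + ROI correlation ---------------------
    perm <- NULL; dmap <- NULL; corrTab <- NULL
    primary <- "DET_vs_HC"
    if (config$n_perm > 0L && primary %in% names(cvs)) {
        sel <- retained$group %in% contrasts[[primary]]
        perm <- permutePerformance(
            features@values[sel, , drop = FALSE], retained$group[sel],
            config$algorithm, nPerm = config$n_perm,
            seed = config$seed, positiveClass = config$positive_class,
            cParam = config$c_param, keepWeights = TRUE)
        writePermutationSummary(perm, file.path(outDir,
                                "permutation_summary.txt"))
        dmap <- discriminativeMap(perm, features, config$alpha,
                                  config$min_cluster,
                                  config$connectivity)
        writeStatVolume(dmap@meanWeight, affine,
                        file.path(outDir, "mean_weight.nii.gz"),
                        "stat=mean_weight")
        writeStatVolume(dmap@voxelP, affine,
                        file.path(outDir, "voxel_p.nii.gz"),
                        "stat=voxel_p")
        utils::write.csv(clusterTable(dmap),
                         file.path(outDir, "clusters.csv"),
                         row.names = FALSE)
        say("permute nperm=%d clusters=%d", config$n_perm,
            length(dmap@clusters))
        detSel <- retained$group == "DET"
        if (length(dmap@clusters) && sum(detSel) >= 12L) {
            roiTab <- extractRoiMeans(maps[detSel], dmap@clusters)
            det <- retained[detSel, ]
            covs <- as.matrix(det[, c("age", "sex", "education",
                                      "trs_ab", "trs_c", "mmse",
                                      "hars14", "fd_power")])
            corrTab <- roiCorrelation(roiTab, zTransform(det$hdrs17),
                                      covs, config$correlation_alpha,
                                      config$bonferroni_mode)
            utils::write.csv(corrTab,
                             file.path(outDir, "roi_correlation.csv"),
                             row.names = FALSE)
            say("correlate rois=%d significant=%d", nrow(corrTab),
                sum(corrTab$significant))
        }
    } else if (config$n_perm == 0L) {
        warning("runPipeline: n_perm = 0; permutation inference skipped")
        say("permute skipped=1")
    }

    # ---- manifest -----------------------------------------------------
    manifest <- c(
        sprintf("package_version: %s",
                as.character(utils::packageVersion("ReHoMVPA"))),
        sprintf("seed: %d", config$seed),
        sprintf("parameters: %s", paste(collapse = " ",
            sprintf("%s=%s", names(unclass(config)),
                    vapply(unclass(config), function(v)
                        paste(format(unlist(v) %||% "NULL"),
                              collapse = ","), character(1))))),
        if (length(inputChecksums))
            sprintf("input_md5: %s=%s", basename(names(inputChecksums)),
                    inputChecksums))
    writeLines(manifest, file.path(outDir, "manifest.txt"))
    say("done output=%s", outDir)

    invisible(list(records = retained, exclusion = excl,
                   features = features, cv = cvs,
                   permutation = perm, discriminative = dmap,
                   correlation = corrTab, metrics = metricsTab,
                   output_dir = outDir))
}

writeConfusion <- function(cv, path) {
    lines <- c(paste0("algorithm: ", cv@algorithm),
               paste0("classes: ", paste(cv@classes, collapse = ", ")),
               "confusion (rows = truth, columns = predicted):",
               utils::capture.output(print(cv@confusion)))
    writeLines(lines, path)
    invisible(path)
}

writePermutationSummary <- function(perm, path) {
    lines <- c(sprintf("n_perm: %d", perm@nPerm),
               sprintf("seed: %d", perm@seed),
               sprintf("%s: observed=%.4f %s", names(perm@observed),
                       perm@observed,
                       formatPermutationP(perm@pValues, perm@nPerm)))
    writeLines(lines, path)
    invisible(path)
}
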