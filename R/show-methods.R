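#' @describeIn BoldSeries-class compact display
#' @param object object to display.
#' @export
setMethod("show", "BoldSeries", function(object) {
    d <- dim(object@data)
    cat("BoldSeries '", object@subjectID, "': ",
        paste(d[1:3], collapse = " x "), " voxels x ", d[4],
        " volumes, TR = ", object@trSeconds, " s\n", sep = "")
})

#' @describeIn ReHoMap-class compact display
#' @param object object to display.
#' @export
setMethod("show", "ReHoMap", function(object) {
    inm <- object@values[object@mask]
    cat("ReHoMap '", object@subjectID, "' (stage ", object@stage, "): ",
        paste(dim(object@values), collapse = " x "), " grid, ",
        sum(object@mask), " in-mask voxels, mean = ",
        signif(mean(inm), 4), "\n", sep = "")
})

#' @describeIn FeatureMatrix-class compact display
#' @param object object to display.
#' @export
setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix: ", nrow(object@values), " subjects x ",
        ncol(object@values), " in-mask voxels (grid ",
        paste(object@gridDim, collapse = " x "), ")\n", sep = "")
})

#' @describeIn CVResult-class compact display
#' @param object object to display.
#' @export
setMethod("show", "CVResult", function(object) {
    cat("CVResult (", object@algorithm, ", leave-one-subject-out, n = ",
        length(object@labels), ")\n", sep = "")
    print(object@confusion)
    binary <- length(object@classes) == 2L
    m <- object@metrics
    if (binary) {
        cat(sprintf(paste0("total accuracy %.2f%%, balanced %.2f%%, ",
                           "sensitivity %.2f%%, specificity %.2f%%\n"),
                    100 * m$total_accuracy, 100 * m$balanced_accuracy,
                    100 * m$sensitivity, 100 * m$specificity))
        if (!is.null(m$auc)) cat(sprintf("AUC %.3f\n", m$auc))
    } else {
        cat(sprintf("total accuracy %.2f%%\n", 100 * m$total_accuracy))
        cat("per-class sensitivity:",
            paste(sprintf("%s %.2f%%", names(m$sensitivity),
                          100 * m$sensitivity), collapse = ", "), "\n")
    }
})

#' @describeIn PermutationResult-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult (", object@nPerm, " permutations, seed ",
        object@seed, ")\n", sep = "")
    for (nm in names(object@observed))
        cat(sprintf("  %s: observed = %.4f, %s\n", nm,
                    object@observed[nm],
                    formatPermutationP(object@pValues[nm],
                                       object@nPerm)))
})

#' @describeIn DiscriminativeMap-class compact display
#' @param object object to display.
#' @export
setMethod("show", "DiscriminativeMap", function(object) {
    cat("DiscriminativeMap: alpha = ", object@alpha,
        ", extent > ", object@minClusterVoxels, " voxels, ",
        length(object@clusters), " cluster(s)\n", sep = "")
    if (length(object@clusters)) print(clusterTable(object))
})

#' @describeIn SyntheticCohort-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SyntheticCohort", function(object) {
    cfg <- object@config
    cat("SyntheticCohort: ", nrow(object@records), " subjects (",
        paste(sprintf("%s=%d", .groupLevels,
                      table(factor(object@records$group,
                                   levels = .groupLevels))),
              collapse = ", "),
        "), grid ", paste(cfg$gridShape, collapse = " x "),
        ", T = ", cfg$nTimepoints, ", seed ", cfg$seed, "\n", sep = "")
})
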