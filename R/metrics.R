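#' Classification performance metrics from a confusion matrix
#'
#' For binary tables (rows = truth, columns = predicted):
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN),
#' balanced accuracy = (sensitivity + specificity)/2, and
#' total accuracy = trace/sum. For multiclass tables, per-class
#' sensitivity, total accuracy and their balanced mean. AUC is computed
#' from decision scores by the rank (Mann-Whitney) statistic when
#' scores are supplied. A metric with a zero denominator is reported as
#' NA (undefined) with a warning, never as 0.
#'
#' @param confusion square integer matrix, rows = truth, columns =
#'   predicted, identical ordered labels on both.
#' @param scores optional held-out decision scores (higher = more
#'   positive-class) for AUC; binary only.
#' @param labels true labels matching `scores`.
#' @param positiveClass row/column treated as positive (default: first).
#' @return named list of metrics as proportions in \[0, 1\].
#' @examples
#' cm <- matrix(c(33L, 8L, 4L, 41L), 2, 2, byrow = TRUE,
#'              dimnames = list(c("P", "N"), c("P", "N")))
#' performanceMetrics(cm, positiveClass = "P")$sensitivity  # 33/41
#' @export
performanceMetrics <- function(confusion, scores = NULL, labels = NULL,
                               positiveClass = NULL) {
    confusion <- as.matrix(confusion)
    if (!nrow(confusion) || nrow(confusion) != ncol(confusion))
        stop("performanceMetrics: confusion matrix must be square and ",
             "non-empty")
    cls <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
    total <- sum(confusion)
    if (total == 0L) stop("performanceMetrics: empty confusion matrix")
    safeDiv <- function(num, den, what) {
        if (den == 0) {
            warning("performanceMetrics: ", what,
                    " undefined (zero denominator); reported as NA")
            return(NA_real_)
        }
        num / den
    }
    totalAccuracy <- sum(diag(confusion)) / total

    if (nrow(confusion) == 2L) {
        positiveClass <- positiveClass %||% cls[1]
        ip <- match(positiveClass, cls)
        io <- setdiff(1:2, ip)
        tp <- confusion[ip, ip]; fn <- confusion[ip, io]
        fp <- confusion[io, ip]; tn <- confusion[io, io]
        sens <- safeDiv(tp, tp + fn, "sensitivity")
        spec <- safeDiv(tn, tn + fp, "specificity")
        out <- list(sensitivity = sens, specificity = spec,
                    ppv = safeDiv(tp, tp + fp, "PPV"),
                    npv = safeDiv(tn, tn + fn, "NPV"),
                    balanced_accuracy = mean(c(sens, spec)),
                    total_accuracy = totalAccuracy,
                    positive_class = positiveClass)
        if (!is.null(scores)) {
            out$auc <- aucRank(scores, labels, positiveClass)
        }
        out
    } else {
        perClass <- vapply(seq_along(cls), function(i)
            safeDiv(confusion[i, i], sum(confusion[i, ]),
                    paste0("sensitivity[", cls[i], "]")), numeric(1))
        names(perClass) <- cls
        list(sensitivity = perClass,
             balanced_accuracy = mean(perClass),
             total_accuracy = totalAccuracy)
    }
}

#' Area under the ROC curve by the rank statistic
#'
#' AUC = P(score of a positive > score of a negative), ties counted
#' one-half; computed from average ranks, identical to all-pairs
#' concordance counting.
#'
#' @param scores decision scores, higher = more positive.
#' @param labels true labels.
#' @param positiveClass label treated as positive.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels, positiveClass) {
    pos <- labels == positiveClass
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0L || nneg == 0L) {
        warning("aucRank: AUC undefined with a single class; NA")
        return(NA_real_)
    }
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve coordinates
#'
#' False-positive and true-positive rates at every distinct score
#' threshold.
#'
#' @inheritParams aucRank
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCoordinates <- function(scores, labels, positiveClass) {
    pos <- labels == positiveClass
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    out <- t(vapply(thr, function(th) {
        pred <- scores >= th
        c(fpr = sum(pred & !pos) / max(sum(!pos), 1L),
          tpr = sum(pred & pos) / max(sum(pos), 1L))
    }, numeric(2)))
    data.frame(threshold = thr, fpr = out[, "fpr"], tpr = out[, "tpr"])
}
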