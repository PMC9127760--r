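#' Assemble a subject-by-voxel feature matrix from smReHo maps
#'
#' Row s, column v holds map s at the v-th in-mask voxel; columns are
#' ordered lexicographically by (i, j, k) grid coordinate, and the
#' coordinate table is kept so weight vectors can be projected back to
#' volume space.
#'
#' @param maps list of [ReHoMap-class] objects sharing grid and mask.
#' @param mask logical 3D array; defaults to the first map's mask.
#' @return a [FeatureMatrix-class] object.
#' @export
buildFeatures <- function(maps, mask = NULL) {
    if (!length(maps)) stop("buildFeatures: no maps supplied")
    if (is.null(mask)) mask <- maps[[1]]@mask
    d <- dim(mask)
    for (m in maps)
        if (!identical(dim(m@values), d))
            stop("buildFeatures: grid mismatch for subject ", m@subjectID)
    co <- maskCoordinates(mask)
    lin <- co[, 1] + (co[, 2] - 1L) * d[1] + (co[, 3] - 1L) * d[1] * d[2]
    vals <- t(vapply(maps, function(m) as.vector(m@values)[lin],
                     numeric(length(lin))))
    new("FeatureMatrix", values = vals, voxelIndex = co,
        gridDim = as.integer(d),
        subjectIDs = vapply(maps, function(m) m@subjectID, character(1)),
        affine = maps[[1]]@affine)
}

#' Project a feature-space weight vector back to a 3D map
#'
#' @param weights length-V numeric vector (one value per feature
#'   column).
#' @param features the [FeatureMatrix-class] the weights refer to.
#' @return 3D array with weights at in-mask voxels, 0 elsewhere.
#' @export
weightsToMap <- function(weights, features) {
    d <- features@gridDim
    out <- array(0, dim = d)
    out[features@voxelIndex] <- weights
    out
}

#' @describeIn buildFeatures raw matrix accessor
#' @param features a [FeatureMatrix-class] object.
#' @export
featureValues <- function(features) features@values

#' Mean-center features by training-set column means
#'
#' Column means are computed on the training rows only and subtracted
#' from both sets, so no information leaks from held-out subjects into
#' the centering statistics.
#'
#' @param train,test numeric matrices with matching columns (`test` may
#'   be NULL).
#' @return list with `train`, `test` and the `means` used.
#' @export
meanCenter <- function(train, test = NULL) {
    mu <- colMeans(train)
    train <- sweep(train, 2L, mu)
    if (!is.null(test)) {
        if (ncol(test) != length(mu))
            stop("meanCenter: column mismatch between train and test")
        test <- sweep(test, 2L, mu)
    }
    list(train = train, test = test, means = mu)
}

#' Fit a linear soft-margin support vector machine
#'
#' Thin wrapper around libsvm (e1071) with a linear kernel and no
#' internal rescaling; the primal weight vector is recovered from the
#' support-vector dual coefficients and oriented so that
#' f(x) = w0 + w'x > 0 predicts the positive class.
#'
#' @param x subjects x features matrix.
#' @param y labels (2 classes).
#' @param cParam soft-margin cost C (default 1).
#' @param positiveClass label treated as positive; defaults to the
#'   alphabetically first.
#' @return a [LinearModel-class] object.
#' @export
fitLinearSVM <- function(x, y, cParam = 1, positiveClass = NULL) {
    y <- as.character(y)
    cls <- sort(unique(y))
    if (length(cls) != 2L)
        stop("fitLinearSVM: exactly 2 classes required, got ",
             length(cls))
    positiveClass <- positiveClass %||% cls[1]
    if (!positiveClass %in% cls)
        stop("fitLinearSVM: positiveClass not present in labels")
    # inputs are validated finite upstream; the identity na.action
    # skips a data.frame round trip that dominates small-fit cost
    fit <- e1071::svm(x = x, y = factor(y, levels = cls),
                      kernel = "linear", cost = cParam, scale = FALSE,
                      na.action = identity)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm orients the decision value toward the first factor level
    if (cls[1] != positiveClass) { w <- -w; b <- -b }
    new("LinearModel", weights = matrix(w, ncol = 1), bias = b,
        classes = c(positiveClass, setdiff(cls, positiveClass)),
        algorithm = "svm", fit = list(svm = fit, cost = cParam))
}

#' Decision values of a linear model
#'
#' @param model a [LinearModel-class] object.
#' @param x subjects x features matrix.
#' @return numeric vector (binary) or matrix (multiclass) of
#'   f(x) = w0 + w'x.
#' @export
decisionValues <- function(model, x) {
    f <- sweep(x %*% model@weights, 2L, model@bias, `+`)
    if (ncol(f) == 1L) drop(f) else f
}

predictLabels <- function(model, x) {
    f <- x %*% model@weights
    f <- sweep(f, 2L, model@bias, `+`)
    if (model@algorithm %in% c("bgpc", "mgpc") ||
        ncol(model@weights) > 1L) {
        model@classes[max.col(f, ties.method = "first")]
    } else {
        ifelse(drop(f) > 0, model@classes[1], model@classes[2])
    }
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject is held out once; the training fold is mean-centered
#' (statistics from the training rows only, applied to the held-out
#' row), the classifier is fitted on the remaining n - 1 subjects, and
#' the held-out subject is predicted. Confusion matrix and performance
#' metrics are assembled from the n held-out predictions. All fits are
#' deterministic, so repeated runs are bit-identical.
#'
#' @param features a [FeatureMatrix-class] or plain subjects x features
#'   matrix.
#' @param labels subject class labels.
#' @param algorithm "svm" (linear SVM), "bgpc" (binary Gaussian-process
#'   classifier) or "mgpc" (multiclass GPC).
#' @param positiveClass positive label for binary metrics; defaults to
#'   the alphabetically first.
#' @param cParam SVM soft-margin cost.
#' @param centerWithinFold if FALSE, centering uses all-subject column
#'   means (the leaky global variant, for comparison only).
#' @param keepWeights store per-fold weight vectors (binary
#'   algorithms).
#' @return a [CVResult-class] object.
#' @export
losocv <- function(features, labels,
                   algorithm = c("svm", "bgpc", "mgpc"),
                   positiveClass = NULL, cParam = 1,
                   centerWithinFold = TRUE, keepWeights = TRUE) {
    algorithm <- match.arg(algorithm)
    x <- if (is(features, "FeatureMatrix")) features@values else
         as.matrix(features)
    y <- as.character(labels)
    n <- nrow(x)
    if (n < 3L) stop("losocv: need at least 3 subjects")
    if (length(y) != n) stop("losocv: one label per subject required")
    cls <- sort(unique(y))
    if (algorithm %in% c("svm", "bgpc") && length(cls) != 2L)
        stop("losocv: '", algorithm, "' requires exactly 2 classes")
    positiveClass <- positiveClass %||% cls[1]
    binary <- length(cls) == 2L
    multiclassModel <- algorithm == "mgpc"

    globalMu <- colMeans(x)
    predicted <- character(n)
    scores <- if (binary) matrix(0, n, 1L,
                                 dimnames = list(NULL, positiveClass))
              else matrix(0, n, length(cls), dimnames = list(NULL, cls))
    storeW <- keepWeights && !multiclassModel
    foldW <- if (storeW) matrix(0, n, ncol(x)) else matrix(0, 0, 0)
    foldB <- numeric(if (storeW) n else 0)

    for (i in seq_len(n)) {
        ytr <- y[-i]
        if (length(unique(ytr)) < 2L)
            stop("losocv: fold ", i, " has a single-class training set")
        if (centerWithinFold) {
            mu <- colMeans(x[-i, , drop = FALSE])
        } else mu <- globalMu
        xtr <- sweep(x[-i, , drop = FALSE], 2L, mu)
        xte <- matrix(x[i, ] - mu, 1L)
        if (algorithm == "svm") {
            # inline fit (same computation as fitLinearSVM, without
            # the per-fold S4 object); inputs validated finite above
            fit <- e1071::svm(x = xtr, y = factor(ytr, levels = cls),
                              kernel = "linear", cost = cParam,
                              scale = FALSE, na.action = identity)
            wv0 <- drop(crossprod(fit$coefs, fit$SV))
            bv0 <- -fit$rho
            if (cls[1] != positiveClass) { wv0 <- -wv0; bv0 <- -bv0 }
            f <- sum(wv0 * xte[1L, ]) + bv0
            predicted[i] <- if (f > 0) positiveClass else
                            setdiff(cls, positiveClass)
            scores[i, 1L] <- f
            if (storeW) {
                foldW[i, ] <- wv0
                foldB[i] <- bv0
            }
        } else {
            model <- fitGPC(xtr, ytr,
                            mode = if (multiclassModel) "multiclass"
                                   else "binary",
                            positiveClass = positiveClass)
            pr <- predictGPC(model, xte)
            if (binary) {
                scores[i, 1L] <- pr[1L, positiveClass]
                predicted[i] <- if (pr[1L, positiveClass] > 0.5)
                    positiveClass else setdiff(cls, positiveClass)
            } else {
                scores[i, ] <- pr[1L, cls]
                predicted[i] <- cls[which.max(pr[1L, cls])]
            }
            if (storeW) {
                wv <- binaryWeights(model, positiveClass)
                foldW[i, ] <- wv$w
                foldB[i] <- wv$b
            }
        }
    }
    conf <- confusionMatrix(y, predicted, cls)
    metr <- performanceMetrics(conf,
                               scores = if (binary) scores[, 1L] else NULL,
                               labels = y, positiveClass = positiveClass)
    new("CVResult", predicted = predicted, scores = scores, labels = y,
        confusion = conf, metrics = metr, foldWeights = foldW,
        foldBias = foldB,
        classes = if (binary) c(positiveClass,
                                setdiff(cls, positiveClass)) else cls,
        algorithm = algorithm)
}

# Positive-class-oriented weight vector of a fitted binary model.
binaryWeights <- function(model, positiveClass) {
    if (ncol(model@weights) == 1L) {
        list(w = model@weights[, 1L], b = model@bias)
    } else {
        ip <- match(positiveClass, model@classes)
        io <- setdiff(seq_along(model@classes), ip)[1]
        list(w = model@weights[, ip] - model@weights[, io],
             b = model@bias[ip] - model@bias[io])
    }
}

confusionMatrix <- function(truth, predicted, classes) {
    tab <- table(factor(truth, levels = classes),
                 factor(predicted, levels = classes))
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    names(dimnames(m)) <- c("truth", "predicted")
    m
}

#' @describeIn losocv confusion-matrix accessor
#' @param cv a [CVResult-class] object.
#' @export
cvConfusion <- function(cv) cv@confusion

#' @describeIn losocv metrics accessor
#' @export
cvMetrics <- function(cv) cv@metrics

#' @describeIn losocv mean across-fold weight vector
#' @export
cvMeanWeights <- function(cv) {
    if (!nrow(cv@foldWeights))
        stop("cvMeanWeights: no fold weights were stored")
    colMeans(cv@foldWeights)
}
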