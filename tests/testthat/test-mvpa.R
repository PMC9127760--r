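test_that("feature assembly is shape-correct, ordered and invertible", {
    mask <- array(FALSE, c(4, 4, 4))
    mask[c(1, 5, 17, 22, 60)] <- TRUE          # 5 scattered voxels
    mkMap <- function(id, seed) {
        set.seed(seed)
        v <- array(0, c(4, 4, 4)); v[mask] <- rexp(5) + 0.1
        v[mask] <- v[mask] / mean(v[mask])
        new("ReHoMap", values = v, mask = mask, stage = "normalized",
            affine = identityAffine(), subjectID = id)
    }
    maps <- list(mkMap("a", 1), mkMap("b", 2), mkMap("c", 3))
    fm <- buildFeatures(maps)
    expect_equal(dim(featureValues(fm)), c(3L, 5L))

    # column 1 maps to the lexicographically first in-mask coordinate
    co <- which(mask, arr.ind = TRUE)
    co <- co[order(co[, 1], co[, 2], co[, 3]), ]
    expect_equal(fm@voxelIndex[1, ], unname(co[1, ]))

    # row -> map -> row round trip
    back <- weightsToMap(featureValues(fm)[2, ], fm)
    expect_equal(back, maps[[2]]@values)

    badMask <- array(TRUE, c(5, 5, 5))
    expect_error(buildFeatures(maps, badMask), "grid mismatch")
})

test_that("mean-centering uses training statistics only", {
    tr <- matrix(c(1, 3, 2, 6), 2)
    te <- matrix(c(2, 4), 1)
    out <- meanCenter(tr, te)
    expect_equal(out$train, matrix(c(-1, 1, -2, 2), 2))
    expect_equal(out$test, matrix(c(0, 0), 1))
    one <- meanCenter(matrix(1:4, 1), matrix(1:4, 1))
    expect_true(all(one$train == 0) && all(one$test == 0))
    set.seed(41)
    big <- meanCenter(matrix(rnorm(200), 20))
    expect_lt(max(abs(colMeans(big$train))), 1e-12)
})

test_that("linear SVM separates symmetric toys and matches a QP oracle", {
    # symmetric 1-D pair: decision boundary at 0
    x <- matrix(c(-1, 1), 2)
    m <- fitLinearSVM(x, c("a", "b"), positiveClass = "b")
    f <- decisionValues(m, x)
    expect_true(f[1] < 0 && f[2] > 0)
    expect_lt(abs(m@bias), 1e-6)

    # separable clouds: perfect training accuracy, and the primal
    # weights match an independent dual quadratic-programming solve
    toy <- makeTwoClassToy(8, 8, p = 3, shift = 4)
    m2 <- fitLinearSVM(toy$x, toy$y, cParam = 1,
                       positiveClass = "case")
    pred <- ifelse(decisionValues(m2, toy$x) > 0, "case", "control")
    expect_equal(pred, toy$y)

    yi <- ifelse(toy$y == "case", 1, -1)
    qp <- kernlab::ipop(c = matrix(-1, 16), H = (yi %*% t(yi)) *
                            (toy$x %*% t(toy$x)),
                        A = matrix(yi, 1), b = 0, l = rep(0, 16),
                        u = rep(1, 16), r = 0)
    wOracle <- drop(t(toy$x) %*% (kernlab::primal(qp) * yi))
    expect_equal(drop(m2@weights), wOracle, tolerance = 1e-3)

    expect_error(fitLinearSVM(toy$x, rep("a", 16)), "2 classes")
})

test_that("duplicated feature columns split their weight", {
    # duplicating a column gives the same kernel as scaling that
    # column by sqrt(2); the two duplicate weights are equal and sum
    # to sqrt(2) times the scaled-fit weight
    toy <- makeTwoClassToy(10, 10, p = 4, shift = 2, seed = 5)
    xd <- cbind(toy$x, toy$x[, 4])
    m2 <- fitLinearSVM(xd, toy$y)
    xs <- toy$x; xs[, 4] <- sqrt(2) * xs[, 4]
    ms <- fitLinearSVM(xs, toy$y)
    expect_equal(m2@weights[4, 1], m2@weights[5, 1], tolerance = 1e-6)
    expect_equal(m2@weights[4, 1] + m2@weights[5, 1],
                 sqrt(2) * ms@weights[4, 1], tolerance = 1e-6)
    expect_equal(m2@weights[1:3, 1], ms@weights[1:3, 1],
                 tolerance = 1e-6)
})

test_that("GPC concentrates probability on well-separated classes", {
    toy <- makeTwoClassToy(12, 12, p = 4, shift = 5, seed = 6)
    m <- fitGPC(toy$x, toy$y, mode = "binary", positiveClass = "case")
    pr <- predictGPC(m, rbind(rnorm(4), rnorm(4) + 5))
    expect_lt(abs(sum(pr[1, ]) - 1), 1e-8)
    expect_gt(pr[1, "case"], 0.9)
    expect_gt(pr[2, "control"], 0.9)
})

test_that("GPC collapses to class frequencies without features", {
    x0 <- matrix(0, 100, 3)
    y0 <- rep(c("a", "b"), c(30, 70))
    m <- fitGPC(x0, y0, mode = "binary")
    pr <- predictGPC(m, matrix(0, 1, 3))
    expect_equal(unname(pr[1, "a"]), 0.3, tolerance = 0.02)
    expect_equal(unname(pr[1, "b"]), 0.7, tolerance = 0.02)
})

test_that("multiclass GPC solves a three-class simplex toy", {
    set.seed(7)
    centers <- rbind(c(4, 0), c(0, 4), c(-4, -4))
    x <- do.call(rbind, lapply(1:3, function(k)
        sweep(matrix(rnorm(24, sd = 0.6), 12), 2, centers[k, ], `+`)))
    y <- rep(c("A", "B", "C"), each = 12)
    cv <- losocv(x, y, algorithm = "mgpc")
    expect_gt(cvMetrics(cv)$total_accuracy, 0.9)
    expect_equal(sum(cvConfusion(cv)), 36L)

    # with two classes the multiclass model degrades to binary behavior
    m2 <- fitGPC(x[1:24, ], y[1:24], mode = "multiclass")
    pr <- predictGPC(m2, x[1:2, , drop = FALSE])
    expect_equal(ncol(pr), 2L)
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-8)
})

test_that("GPC agrees with an independent kernel-machine on easy data", {
    toy <- makeTwoClassToy(10, 10, p = 3, shift = 4, seed = 8)
    m <- fitGPC(toy$x, toy$y, mode = "binary", positiveClass = "case")
    own <- predictGPC(m, toy$x)[, "case"] > 0.5
    ref <- kernlab::gausspr(toy$x, factor(toy$y),
                            kernel = "vanilladot", kpar = list())
    refPred <- kernlab::predict(ref, toy$x) == "case"
    expect_equal(own, unname(refPred))
})

test_that("leave-one-subject-out honors its fold contract", {
    toy <- makeTwoClassToy(8, 8, p = 5, shift = 5, seed = 9)
    cv <- losocv(toy$x, toy$y, "svm", positiveClass = "case")
    expect_length(cv@predicted, 16L)
    expect_equal(sum(cvConfusion(cv)), 16L)
    expect_equal(cvMetrics(cv)$total_accuracy, 1)
    expect_equal(dim(cv@foldWeights), c(16L, 5L))

    # deterministic: repeated runs bit-match
    cv2 <- losocv(toy$x, toy$y, "svm", positiveClass = "case")
    expect_identical(cv@scores, cv2@scores)
    expect_identical(cv@foldWeights, cv2@foldWeights)

    expect_error(losocv(toy$x[1:2, ], toy$y[1:2], "svm"),
                 "at least 3")
    # a class with one member forces a single-class training fold
    expect_error(losocv(toy$x[c(1, 9:12), ], toy$y[c(1, 9:12)], "svm"),
                 "single-class")
})

test_that("shuffled labels drop accuracy to chance", {
    set.seed(10)
    toy <- makeTwoClassToy(12, 12, p = 6, shift = 0, seed = 10)
    cv <- losocv(toy$x, sample(toy$y), "svm")
    # central 99% binomial band around 0.5 for n = 24
    band <- qbinom(c(0.005, 0.995), 24, 0.5) / 24
    acc <- cvMetrics(cv)$total_accuracy
    expect_gte(acc, band[1])
    expect_lte(acc, band[2])
})

test_that("centering statistics ignore the held-out subject", {
    toy <- makeTwoClassToy(6, 6, p = 3, shift = 3, seed = 11)
    x <- toy$x
    x[1, ] <- x[1, ] + 1e4          # extreme held-out subject
    cvIn <- losocv(x, toy$y, "svm")
    cvGlobal <- losocv(x, toy$y, "svm", centerWithinFold = FALSE)
    # fold 2 trains on rows != 2; within-fold centering includes the
    # extreme row 1 only through training data, global centering leaks
    # nothing extra here -- but the two decision scores for subject 1
    # itself must differ, proving the centering path is fold-local
    expect_false(isTRUE(all.equal(cvIn@scores[1, ], cvGlobal@scores[1, ])))
    # and with within-fold centering, fold 1's training means equal the
    # column means of the other 11 subjects exactly
    mu <- colMeans(x[-1, ])
    ctr <- meanCenter(x[-1, ], x[1, , drop = FALSE])
    expect_equal(ctr$means, mu)
})

test_that("weight maps localize a strong implanted effect", {
    box <- effectRegion(c(3, 3, 3), c(6, 6, 6), c(0.85, 0.85, 0.05))
    co <- tinyCohort(grid = c(10, 10, 10), tt = 60,
                     groups = c(8, 0, 8), regions = list(box),
                     seed = 12)
    maps <- lapply(co$series, smReHo, mask = co$mask)
    fm <- buildFeatures(maps, co$mask)
    cv <- losocv(fm, co$records$group, "svm", positiveClass = "DET")
    w <- abs(cvMeanWeights(cv))
    top <- fm@voxelIndex[order(w, decreasing = TRUE)[1:64], ]
    inBox <- top[, 1] >= 3 & top[, 1] <= 6 & top[, 2] >= 3 &
             top[, 2] <= 6 & top[, 3] >= 3 & top[, 3] <= 6
    dice <- 2 * sum(inBox) / (64 + 64)
    expect_gt(dice, 0.5)
})
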