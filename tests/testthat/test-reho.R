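test_that("Kendall's W reproduces hand-worked and boundary cases", {
    # 27 rank-identical series: perfect concordance
    x <- matrix(rep(sort(rnorm(40)), 27), 27, byrow = TRUE)
    expect_equal(computeKCC(x), 1)

    # hand-worked rank-sum case: R = (6,7,8,9), Rbar = 7.5, W = 5/45
    y <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
    expect_equal(computeKCC(y), 5 / 45, tolerance = 1e-12)
    expect_equal(naiveKCC(y), 5 / 45, tolerance = 1e-12)

    expect_error(computeKCC(matrix(1:5, 1)), "K >= 2")
    expect_warning(w0 <- computeKCC(matrix(2, 3, 6)), "constant")
    expect_equal(w0, 0)
})

test_that("Kendall's W matches the brute-force oracle on random sets", {
    set.seed(31)
    for (rep in 1:25) {
        k <- sample(2:27, 1)
        n <- sample(5:50, 1)
        x <- matrix(rnorm(k * n), k)
        expect_equal(computeKCC(x), naiveKCC(x), tolerance = 1e-10)
    }
})

test_that("W is a rank statistic: invariances hold", {
    set.seed(32)
    x <- matrix(rnorm(27 * 30), 27)
    w <- computeKCC(x)
    # strictly monotone transform of one series
    x2 <- x; x2[5, ] <- exp(3 * x2[5, ]) + 2
    expect_equal(computeKCC(x2), w, tolerance = 1e-12)
    # permuting the order of the K series
    expect_equal(computeKCC(x[sample(27), ]), w, tolerance = 1e-12)
    # appending an independent series to a concordant set lowers W
    conc <- matrix(rep(rnorm(30), 10), 10, byrow = TRUE)
    expect_lt(computeKCC(rbind(conc, rnorm(30))), 1)
})

test_that("the ReHo map equals the per-voxel loop oracle", {
    set.seed(33)
    arr <- array(rnorm(6 * 6 * 6 * 25), c(6, 6, 6, 25))
    mask <- array(TRUE, c(6, 6, 6))
    mask[1:2, 1:2, 1:2] <- FALSE          # irregular mask edge
    got <- rehoMap(boldSeries(arr, subjectID = "o"), mask)
    want <- naiveReHoMap(arr, mask)
    expect_equal(got@values, want, tolerance = 1e-12)
    expect_true(all(got@values[!mask] == 0))
})

test_that("identical series give W = 1 at every in-mask voxel", {
    arr <- array(rep(rnorm(30), each = 5 * 5 * 5), c(5, 5, 5, 30))
    m <- rehoMap(boldSeries(arr))
    expect_true(all(abs(m@values - 1) < 1e-12))
})

test_that("white-noise maps have small W that decreases with n", {
    set.seed(34)
    mk <- function(tt) {
        arr <- array(rnorm(7^3 * tt), c(7, 7, 7, tt))
        mean(rehoMap(boldSeries(arr))@values)
    }
    w60 <- mk(60); w230 <- mk(230)
    expect_lt(w230, 0.1)
    expect_lt(w230, w60)
})

test_that("interior voxels agree with an explicitly gathered 27-set", {
    set.seed(35)
    arr <- array(rnorm(5^3 * 30), c(5, 5, 5, 30))
    m <- rehoMap(boldSeries(arr))
    nb <- list()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
        nb[[length(nb) + 1L]] <- arr[3 + di, 3 + dj, 3 + dk, ]
    expect_equal(m@values[3, 3, 3], computeKCC(do.call(rbind, nb)),
                 tolerance = 1e-12)
})

test_that("strict-neighborhood mode zeroes voxels without full 27-sets", {
    set.seed(36)
    arr <- array(rnorm(5^3 * 25), c(5, 5, 5, 25))
    m <- rehoMap(boldSeries(arr), requireFullNeighborhood = TRUE)
    expect_equal(m@values[1, 3, 3], 0)
    expect_gt(m@values[3, 3, 3], 0)
})

test_that("global-mean normalization is exact", {
    set.seed(37)
    arr <- array(rnorm(5^3 * 25), c(5, 5, 5, 25))
    raw <- rehoMap(boldSeries(arr))
    norm <- normalizeGlobalMean(raw)
    expect_equal(mean(norm@values[norm@mask]), 1, tolerance = 1e-12)
    expect_equal(mapStage(norm), "normalized")

    # constant map: every in-mask value becomes exactly 1
    cst <- raw; cst@values[cst@mask] <- 0.4
    expect_true(all(normalizeGlobalMean(cst)@values[cst@mask] == 1))

    # two-voxel arithmetic: {0.2, 0.6} -> {0.5, 1.5}
    mask2 <- array(FALSE, c(3, 3, 3)); mask2[c(1, 14)] <- TRUE
    v2 <- array(0, c(3, 3, 3)); v2[c(1, 14)] <- c(0.2, 0.6)
    m2 <- new("ReHoMap", values = v2, mask = mask2, stage = "raw",
              affine = identityAffine(), subjectID = "t")
    expect_equal(normalizeGlobalMean(m2)@values[c(1, 14)], c(0.5, 1.5))
})

test_that("Gaussian smoothing has the right kernel and identities", {
    mask <- array(TRUE, c(9, 9, 9))
    base <- array(0, c(9, 9, 9))
    mk <- function(vals) {
        v <- vals
        v[mask] <- v[mask] / mean(v[mask])
        new("ReHoMap", values = v, mask = mask, stage = "normalized",
            affine = identityAffine(c(3, 3, 3)), subjectID = "t")
    }
    # constants are preserved
    cst <- mk(array(1, c(9, 9, 9)))
    sm <- smoothGaussian(cst, 4)
    expect_equal(sm@values, cst@values, tolerance = 1e-10)
    expect_equal(mapStage(sm), "smoothed")

    # single interior spike spreads with sigma = 4 / (2.3548 * 3) voxels
    spike <- base; spike[5, 5, 5] <- 1e6
    smk <- smoothGaussian(mk(spike), 4)
    sigma <- 4 / sqrt(8 * log(2)) / 3
    expect_equal(sigma, 0.5665, tolerance = 1e-3)
    ratio <- smk@values[6, 5, 5] / smk@values[5, 5, 5]
    expect_equal(ratio, exp(-1 / (2 * sigma^2)), tolerance = 0.01)

    # in-mask total is approximately preserved for interior signal
    expect_equal(sum(smk@values), sum(mk(spike)@values),
                 tolerance = 0.02)

    # non-positive width: identity with a warning
    expect_warning(ident <- smoothGaussian(cst, 0), "unsmoothed")
    expect_equal(ident@values, cst@values)
})
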