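mkClusterMap <- function(vals, mask = NULL) {
    d <- dim(vals)
    if (is.null(mask)) mask <- array(TRUE, d)
    new("ReHoMap", values = vals, mask = mask, stage = "smoothed",
        affine = identityAffine(), subjectID = paste0("s", sample(1e6, 1)))
}

test_that("ROI means equal the per-voxel averaging oracle", {
    set.seed(71)
    d <- c(6, 6, 6)
    maps <- lapply(1:4, function(i) mkClusterMap(array(rexp(216), d)))
    vox1 <- as.matrix(expand.grid(2:3, 2:3, 2:3))
    vox2 <- matrix(c(5L, 5L, 5L), 1)
    cl <- list(new("ClusterROI", voxels = vox1, peak = c(2L, 2L, 2L),
                   sign = "positive", label = "a"),
               new("ClusterROI", voxels = vox2, peak = c(5L, 5L, 5L),
                   sign = "negative", label = "b"))
    tab <- extractRoiMeans(maps, cl)
    expect_equal(dim(tab), c(4L, 2L))
    for (s in 1:4) {
        acc <- 0
        for (r in seq_len(nrow(vox1)))
            acc <- acc + maps[[s]]@values[vox1[r, 1], vox1[r, 2],
                                          vox1[r, 3]]
        expect_equal(tab[s, 1], acc / nrow(vox1), tolerance = 1e-12)
        expect_equal(tab[s, 2], maps[[s]]@values[5, 5, 5])
    }
    # constant map: every ROI mean equals the constant
    cmap <- mkClusterMap(array(2.5, d))
    expect_true(all(extractRoiMeans(list(cmap), cl) == 2.5))
})

test_that("partial correlation reduces to plain Pearson and is affine
           invariant", {
    set.seed(72)
    x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.5)
    plain <- partialPearson(x, y)
    ct <- cor.test(x, y)
    expect_equal(plain$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(plain$p, ct$p.value, tolerance = 1e-12)

    expect_equal(partialPearson(x, x)$r, 1)

    z <- matrix(rnorm(60), 30)
    a <- partialPearson(x, y, z)
    b <- partialPearson(2 * x - 7, -3 * y + 1, cbind(5 * z[, 1] + 2,
                                                     z[, 2] / 4))
    expect_equal(abs(a$r), abs(b$r), tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)

    # x fully explained by the covariates: undefined, flagged
    expect_warning(res <- partialPearson(z[, 1], y,
                                         cbind(z[, 1])), "undefined")
    expect_true(is.na(res$r))
    expect_error(partialPearson(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
                 "n >")
})

test_that("partial correlation matches a residual-regression oracle", {
    set.seed(73)
    n <- 40
    z <- matrix(rnorm(3 * n), n)
    x <- z %*% c(1, -1, 2) + rnorm(n)
    y <- z %*% c(0.5, 1, 0) - 0.4 * x + rnorm(n)
    got <- partialPearson(x, y, z)
    rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
    expect_equal(got$r, unname(cor(rx, ry)), tolerance = 1e-12)
    tref <- got$r * sqrt((n - 3 - 2) / (1 - got$r^2))
    expect_equal(got$p, 2 * pt(-abs(tref), n - 5), tolerance = 1e-12)
})

test_that("Bonferroni thresholds cover both counting conventions", {
    expect_equal(bonferroniThreshold(0.05, 18), 0.05 / 18)
    expect_equal(round(bonferroniThreshold(0.05, 18), 6), 0.002778)
    expect_equal(bonferroniThreshold(0.05, 153), 0.05 / 153)
    expect_equal(bonferroniThreshold(0.05, 18, "pairwise"),
                 0.05 / 153)     # 18 * 17 / 2 = 153
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    expect_error(bonferroniThreshold(0.05, 0), "m")
})

test_that("z-transform standardizes and is idempotent", {
    z <- zTransform(c(1, 2, 3))
    expect_equal(z, c(-1, 0, 1))            # sample-SD convention
    expect_equal(mean(z), 0)
    expect_equal(sd(z), 1)
    set.seed(74)
    v <- rnorm(50, 10, 3)
    expect_equal(zTransform(zTransform(v)), zTransform(v),
                 tolerance = 1e-12)
    expect_error(zTransform(rep(2, 10)), "zero variance")
    expect_error(zTransform(1), "at least 2")
})

test_that("planted severity couplings are recovered with correct signs", {
    posBox <- effectRegion(c(2, 2, 2), c(4, 4, 4), c(0.6, 0, 0),
                           hdrsCoupling = 40)
    negBox <- effectRegion(c(6, 6, 6), c(8, 8, 8), c(0.6, 0, 0),
                           hdrsCoupling = -40)
    okPos <- 0L; okNeg <- 0L
    reps <- 20
    for (r in seq_len(reps)) {
        co <- generateCohort(syntheticConfig(
            gridShape = c(9, 9, 9), nTimepoints = 40,
            groupSizes = c(16, 0, 0),
            effectRegions = list(posBox, negBox),
            coherenceSD = 0.12, seed = 7000 + r))
        maps <- lapply(co$series, smReHo, mask = co$mask)
        cl <- list(new("ClusterROI",
                       voxels = as.matrix(expand.grid(2:4, 2:4, 2:4)),
                       peak = c(3L, 3L, 3L), sign = "positive",
                       label = "pos"),
                   new("ClusterROI",
                       voxels = as.matrix(expand.grid(6:8, 6:8, 6:8)),
                       peak = c(7L, 7L, 7L), sign = "negative",
                       label = "neg"))
        tab <- extractRoiMeans(maps, cl)
        covs <- as.matrix(co$records[, c("age", "sex", "fd_power")])
        rp <- partialPearson(tab[, 1], co$records$hdrs17, covs)$r
        rn <- partialPearson(tab[, 2], co$records$hdrs17, covs)$r
        if (rp > 0) okPos <- okPos + 1L
        if (rn < 0) okNeg <- okNeg + 1L
    }
    expect_gte(okPos / reps, 0.9)
    expect_gte(okNeg / reps, 0.9)
})

test_that("the ROI correlation table flags Bonferroni survivors", {
    set.seed(75)
    n <- 40
    sev <- rnorm(n)
    roi <- cbind(strong = sev + rnorm(n, sd = 0.2),
                 null1 = rnorm(n), null2 = rnorm(n))
    tab <- roiCorrelation(roi, sev)
    expect_equal(nrow(tab), 3L)
    expect_true(tab$significant[tab$roi == "strong"])
    expect_equal(tab$threshold, rep(0.05 / 3, 3))
})
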