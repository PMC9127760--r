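makeSeries <- function(mat, tr = 2) {
    # mat: T x V with V a cube-compatible count; use a 3x3x3 grid
    v <- ncol(mat)
    stopifnot(v == 27L)
    boldSeries(array(t(mat), dim = c(3, 3, 3, nrow(mat))),
               trSeconds = tr)
}

test_that("framewise displacement matches its definition", {
    expect_error(fdPower(matrix(0, 10, 5)), "6 columns")
    res <- fdPower(matrix(1.5, 10, 6))
    expect_equal(res$fd, rep(0, 10))
    expect_equal(res$meanFD, 0)

    m <- matrix(0, 10, 6); m[2:10, 1] <- 0.1   # one 0.1 mm step at t=2
    res <- fdPower(m)
    expect_equal(res$fd[2], 0.1)
    expect_equal(res$meanFD, 0.1 / 10)

    set.seed(4)
    m <- matrix(rnorm(20 * 6, sd = 0.05), 20, 6)
    expect_equal(fdPower(m)$fd, naiveFD(m), tolerance = 1e-12)
})

test_that("motion gate excludes strictly above the threshold", {
    recs <- data.frame(subject_id = c("a", "b", "c"),
                       fd_power = c(0.19, 0.20, 0.21))
    out <- excludeByMotion(recs)
    expect_equal(out$retained$subject_id, c("a", "b"))
    expect_equal(out$excluded, "c")
    empty <- excludeByMotion(recs[0, ])
    expect_equal(nrow(empty$retained), 0L)
})

test_that("Friston-24 expansion has the documented structure", {
    m <- matrix(seq_len(30) / 10, 5, 6)
    f24 <- friston24(m)
    expect_equal(dim(f24), c(5L, 24L))
    expect_equal(f24[, 1:6], m)
    expect_equal(f24[, 7:12], m^2)
    expect_equal(f24[1, 13:24], rep(0, 12))     # no lag before t=1
    expect_equal(f24[2:5, 13:18], m[1:4, ])
})

test_that("confound regression equals least squares and orthogonalizes", {
    set.seed(8)
    tt <- 40
    mat <- matrix(rnorm(tt * 27), tt)
    m6 <- matrix(rnorm(tt * 6, sd = 0.02), tt)
    gl <- rowMeans(mat)
    cs <- confoundSet(motion6 = m6, global = gl)
    out <- regressConfounds(makeSeries(mat), cs)
    res <- t(matrix(out@data, 27, tt))
    # brute-force normal-equation oracle
    x <- cbind(1, friston24(m6), gl)
    beta <- solve(t(x) %*% x, t(x) %*% mat)
    expect_equal(res, mat - x %*% beta, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_lt(max(abs(crossprod(x, res))) / tt, 1e-8)

    # a voxel equal to the global signal is fully removed
    mat2 <- mat; mat2[, 5] <- gl
    out2 <- regressConfounds(makeSeries(mat2),
                             confoundSet(global = gl))
    res2 <- t(matrix(out2@data, 27, tt))
    expect_lt(max(abs(res2[, 5])), 1e-10)

    # collinear columns are dropped with a warning, not an error
    expect_warning(
        regressConfounds(makeSeries(mat),
                         confoundSet(wm = gl, csf = gl)),
        "collinear")
})

test_that("linear detrending removes exactly degree-1 structure", {
    tt <- 30
    tvec <- seq_len(tt)
    lin <- matrix(rep(2 * tvec + 5, 27), tt)
    expect_lt(max(abs(detrendLinear(makeSeries(lin))@data)), 1e-10)
    const <- matrix(3, tt, 27)
    expect_lt(max(abs(detrendLinear(makeSeries(const))@data)), 1e-12)
    set.seed(9)
    mat <- matrix(rnorm(tt * 27), tt)
    out <- t(matrix(detrendLinear(makeSeries(mat))@data, 27, tt))
    x <- cbind(1, tvec)
    beta <- solve(t(x) %*% x, t(x) %*% mat)
    expect_equal(out, mat - x %*% beta, tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("band-pass keeps the band and removes the rest", {
    tt <- 200; tr <- 2
    tvec <- seq_len(tt) * tr
    inband <- sin(2 * pi * 0.04 * tvec)          # on-bin at T=200
    outband <- sin(2 * pi * 0.2 * tvec)
    mat <- cbind(matrix(inband, tt, 13), matrix(outband, tt, 14))
    out <- t(matrix(bandpassFilter(makeSeries(mat, tr))@data, 27, tt))
    ratio <- sd(out[, 1]) / sd(inband)
    expect_lt(abs(ratio - 1), 0.05)
    expect_lt(sd(out[, 27]) / sd(outband), 0.1)  # >= 90% attenuation
    # zero phase: the in-band sinusoid is not shifted (a one-sample
    # lag at 0.04 Hz would already cap the correlation near 0.87)
    expect_gt(cor(out[, 1], inband), 0.99)
    lagged <- cor(out[-tt, 1], inband[-1])
    expect_gt(cor(out[, 1], inband), lagged)

    expect_error(bandpassFilter(makeSeries(mat, tr), 0.01, 0.3),
                 "Nyquist")
})

test_that("band-passed white noise concentrates spectral mass in band", {
    set.seed(10)
    tt <- 230; tr <- 2
    mat <- matrix(rnorm(tt * 27), tt)
    out <- t(matrix(bandpassFilter(makeSeries(mat, tr))@data, 27, tt))
    spec <- Mod(stats::mvfft(out))^2
    freq <- (seq_len(tt) - 1) / (tt * tr)
    freq <- pmin(freq, 1 / tr - freq)
    inBand <- freq >= 0.01 & freq <= 0.08
    mass <- sum(spec[inBand, ]) / sum(spec)
    expect_gt(mass, 0.8)
})

test_that("the composed preprocessing chain is idempotent", {
    set.seed(11)
    tt <- 230
    mat <- matrix(rnorm(tt * 27), tt) + 5
    s <- makeSeries(mat)
    once <- preprocessBold(s)
    twice <- preprocessBold(once)
    rmsChange <- sqrt(mean((twice@data - once@data)^2)) /
        sqrt(mean(once@data^2))
    expect_lt(rmsChange, 0.01)
})

test_that("preprocessing commutes with voxel permutation", {
    set.seed(12)
    tt <- 40
    mat <- matrix(rnorm(tt * 27), tt)
    perm <- sample(27)
    a <- preprocessBold(makeSeries(mat))
    b <- preprocessBold(makeSeries(mat[, perm]))
    am <- t(matrix(a@data, 27, tt))
    bm <- t(matrix(b@data, 27, tt))
    expect_equal(bm, am[, perm], tolerance = 1e-12)
})
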