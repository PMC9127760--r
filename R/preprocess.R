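#' Construct a BoldSeries
#'
#' @param data numeric 4D array (X x Y x Z x T).
#' @param trSeconds repetition time in seconds.
#' @param affine 4 x 4 voxel-to-mm transform; default 3 mm isotropic.
#' @param subjectID subject identifier.
#' @return a [BoldSeries-class] object.
#' @export
boldSeries <- function(data, trSeconds = 2, affine = identityAffine(),
                       subjectID = "subject") {
    new("BoldSeries", data = data, trSeconds = trSeconds,
        affine = affine, subjectID = subjectID)
}

# Time x voxel view of a BoldSeries and its inverse.
seriesMatrix <- function(series) {
    d <- dim(series@data)
    t(matrix(series@data, prod(d[1:3]), d[4]))
}

replaceSeriesMatrix <- function(series, mat) {
    d <- dim(series@data)
    series@data <- array(t(mat), dim = d)
    series
}

#' Framewise displacement (Power)
#'
#' Per-volume head-motion summary: the sum of the absolute backward
#' differences of the six realignment parameters, with rotations
#' converted to arc length on a sphere of the given radius. The first
#' element is 0.
#'
#' @param motion6 T x 6 matrix; columns 1-3 translations (mm), 4-6
#'   rotations (radians).
#' @param rotationRadiusMM sphere radius for the rotation-to-arc-length
#'   conversion (default 50 mm).
#' @return list with `fd` (length-T vector) and `meanFD`.
#' @examples
#' m <- matrix(0, 10, 6); m[2, 1] <- 0.1
#' fdPower(m)$meanFD   # 0.1 / 10
#' @export
fdPower <- function(motion6, rotationRadiusMM = 50) {
    motion6 <- as.matrix(motion6)
    if (ncol(motion6) != 6L)
        stop("fdPower: 'motion6' must have exactly 6 columns")
    if (nrow(motion6) < 2L)
        stop("fdPower: need at least 2 time points")
    d <- diff(motion6)
    d[, 4:6] <- d[, 4:6] * rotationRadiusMM
    fd <- c(0, rowSums(abs(d)))
    list(fd = fd, meanFD = mean(fd))
}

#' Exclude subjects by head motion
#'
#' Retains subjects whose mean FDpower is at or below the threshold;
#' subjects strictly above it are excluded (the gate is "greater than").
#'
#' @param records data.frame with columns `subject_id` and `fd_power`.
#' @param thresholdMM exclusion threshold in mm (default 0.2).
#' @return list with `retained` (data.frame), `excluded` (subject ids)
#'   and `report` (data.frame of id, fd_power, retained flag).
#' @export
excludeByMotion <- function(records, thresholdMM = 0.2) {
    if (nrow(records) == 0L)
        return(list(retained = records, excluded = character(0),
                    report = data.frame(subject_id = character(0),
                                        fd_power = numeric(0),
                                        retained = logical(0))))
    keep <- records$fd_power <= thresholdMM
    list(retained = records[keep, , drop = FALSE],
         excluded = records$subject_id[!keep],
         report = data.frame(subject_id = records$subject_id,
                             fd_power = records$fd_power,
                             retained = keep))
}

#' Friston-24 expansion of six realignment parameters
#'
#' Builds \{p, p^2, p(t-1), p(t-1)^2\} for each of the six parameters;
#' the lagged terms of the first volume are set to 0.
#'
#' @param motion6 T x 6 matrix of realignment parameters.
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion6) {
    motion6 <- as.matrix(motion6)
    if (ncol(motion6) != 6L)
        stop("friston24: 'motion6' must have exactly 6 columns")
    lag1 <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
    cbind(motion6, motion6^2, lag1, lag1^2)
}

#' Assemble a nuisance-regressor set
#'
#' @param motion6 T x 6 realignment parameters (expanded internally to
#'   Friston-24), or NULL.
#' @param wm,csf,global length-T white-matter, CSF and whole-brain mean
#'   signals (any may be NULL).
#' @return a [ConfoundSet-class] object.
#' @export
confoundSet <- function(motion6 = NULL, wm = NULL, csf = NULL,
                        global = NULL) {
    m24 <- if (is.null(motion6)) matrix(0, 0, 0) else friston24(motion6)
    new("ConfoundSet", motion24 = m24,
        wm = as.numeric(wm %||% numeric(0)),
        csf = as.numeric(csf %||% numeric(0)),
        global = as.numeric(global %||% numeric(0)))
}

confoundDesign <- function(confounds, tt) {
    cols <- list()
    if (ncol(confounds@motion24)) {
        if (nrow(confounds@motion24) != tt)
            stop("regressConfounds: motion parameters have ",
                 nrow(confounds@motion24), " rows but the series has ",
                 tt, " volumes")
        cols$motion <- confounds@motion24
    }
    for (nm in c("wm", "csf", "global")) {
        v <- slot(confounds, nm)
        if (length(v)) {
            if (length(v) != tt)
                stop("regressConfounds: '", nm, "' length mismatch")
            cols[[nm]] <- v
        }
    }
    do.call(cbind, c(list(intercept = rep(1, tt)), cols))
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary-least-squares residualization against
#' \[intercept | Friston-24 motion | WM | CSF | global\]. Collinear
#' columns are dropped with a warning; residuals are orthogonal to every
#' retained regressor.
#'
#' @param series a [BoldSeries-class] object.
#' @param confounds a [ConfoundSet-class] object (see [confoundSet()]).
#' @return the residual [BoldSeries-class].
#' @export
regressConfounds <- function(series, confounds) {
    y <- seriesMatrix(series)
    x <- confoundDesign(confounds, nrow(y))
    qrx <- qr(x)
    if (qrx$rank < ncol(x)) {
        dropped <- colnames(x)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(x))]]
        warning("regressConfounds: dropping collinear regressor(s): ",
                paste(unique(dropped), collapse = ", "))
        x <- x[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
        qrx <- qr(x)
    }
    res <- qr.resid(qrx, y)
    replaceSeriesMatrix(series, res)
}

#' Remove the per-voxel linear trend
#'
#' First-order polynomial detrending in time (intercept + slope), the
#' standard correction for slow scanner drift.
#'
#' @param series a [BoldSeries-class] object.
#' @return the detrended [BoldSeries-class].
#' @export
detrendLinear <- function(series) {
    y <- seriesMatrix(series)
    tt <- nrow(y)
    if (tt < 3L) stop("detrendLinear: need at least 3 time points")
    x <- cbind(1, seq_len(tt))
    res <- qr.resid(qr(x), y)
    replaceSeriesMatrix(series, res)
}

#' Temporal band-pass filter
#'
#' Zero-phase ideal (frequency-domain) band-pass: Fourier components
#' with frequency inside \[lowHz, highHz\] are kept, all others
#' (including the DC/mean component) are removed; the in-band component
#' of the linear-trend direction is then projected out as well, so the
#' filter is an orthogonal projection onto in-band, trend-free signal
#' space. This is the projection formulation used by the standard
#' resting-state toolchains: it is exactly idempotent (also when
#' composed with [detrendLinear()]), and being symmetric it introduces
#' no temporal shift.
#'
#' @param series a [BoldSeries-class] object.
#' @param lowHz,highHz pass-band edges in Hz (defaults 0.01-0.08).
#' @return the filtered [BoldSeries-class].
#' @export
bandpassFilter <- function(series, lowHz = 0.01, highHz = 0.08) {
    tr <- series@trSeconds
    nyquist <- 1 / (2 * tr)
    if (highHz >= nyquist || lowHz >= highHz || lowHz < 0)
        stop("bandpassFilter: band [", lowHz, ", ", highHz,
             "] Hz is invalid for TR = ", tr,
             " s (Nyquist = ", nyquist, " Hz)")
    y <- seriesMatrix(series)
    tt <- nrow(y)
    freq <- (seq_len(tt) - 1) / (tt * tr)
    freq <- pmin(freq, 1 / tr - freq)      # two-sided spectrum
    keep <- freq >= lowHz & freq <= highHz
    maskFFT <- function(m) {
        mf <- stats::mvfft(m)
        mf[!keep, ] <- 0
        Re(stats::mvfft(mf, inverse = TRUE)) / tt
    }
    res <- maskFFT(y)
    # project out the in-band part of the linear-trend direction
    lperp <- drop(maskFFT(matrix(seq_len(tt) - (tt + 1) / 2)))
    nl <- sum(lperp^2)
    if (nl > 0)
        res <- res - lperp %*% (crossprod(lperp, res) / nl)
    replaceSeriesMatrix(series, res)
}

#' Temporal preprocessing chain
#'
#' Nuisance regression, then linear detrending, then band-pass
#' filtering, in that order.
#'
#' @param series a [BoldSeries-class] object.
#' @param confounds optional [ConfoundSet-class]; skipped if NULL.
#' @param lowHz,highHz band-pass edges in Hz.
#' @return the preprocessed [BoldSeries-class].
#' @export
preprocessBold <- function(series, confounds = NULL, lowHz = 0.01,
                           highHz = 0.08) {
    if (!is.null(confounds))
        series <- regressConfounds(series, confounds)
    series <- detrendLinear(series)
    bandpassFilter(series, lowHz, highHz)
}
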