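# Independent brute-force oracles used to validate the fast
# implementations. These deliberately re-derive each quantity from its
# definition with plain loops.

# Kendall's W from its definition: rank each series over time, sum
# ranks per time point, plug into the concordance formula.
naiveKCC <- function(x) {
    k <- nrow(x); n <- ncol(x)
    ranks <- matrix(0, k, n)
    for (i in seq_len(k)) ranks[i, ] <- rank(x[i, ])
    ri <- numeric(n)
    for (tp in seq_len(n)) ri[tp] <- sum(ranks[, tp])
    rbar <- (n + 1) * k / 2
    num <- sum(ri^2) - n * rbar^2
    den <- k * k * (n^3 - n) / 12
    num / den
}

# Per-voxel loop ReHo: gather the in-mask 27-neighborhood explicitly
# and apply naiveKCC.
naiveReHoMap <- function(arr4d, mask) {
    d <- dim(arr4d)[1:3]
    out <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            if (!mask[i, j, k]) next
            nb <- list()
            for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
                ii <- i + di; jj <- j + dj; kk <- k + dk
                if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
                    kk < 1 || kk > d[3]) next
                if (!mask[ii, jj, kk]) next
                nb[[length(nb) + 1L]] <- arr4d[ii, jj, kk, ]
            }
            if (length(nb) < 2L) next
            out[i, j, k] <- naiveKCC(do.call(rbind, nb))
        }
    out
}

# Power framewise displacement, re-derived element by element.
naiveFD <- function(m, radius = 50) {
    tt <- nrow(m)
    fd <- numeric(tt)
    for (t in 2:tt) {
        s <- 0
        for (c in 1:3) s <- s + abs(m[t, c] - m[t - 1, c])
        for (c in 4:6) s <- s + radius * abs(m[t, c] - m[t - 1, c])
        fd[t] <- s
    }
    fd
}

# All-pairs concordance AUC with half-credit for ties.
naiveAUC <- function(scores, labels, positiveClass) {
    pos <- which(labels == positiveClass)
    neg <- which(labels != positiveClass)
    s <- 0
    for (i in pos) for (j in neg) {
        if (scores[i] > scores[j]) s <- s + 1
        else if (scores[i] == scores[j]) s <- s + 0.5
    }
    s / (length(pos) * length(neg))
}

# Small separable feature set for classifier tests: two shifted
# Gaussian clouds.
makeTwoClassToy <- function(n1 = 10, n2 = 10, p = 4, shift = 3,
                            seed = 42) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(n1 * p), n1),
               matrix(rnorm(n2 * p) + shift, n2))
    list(x = x, y = rep(c("case", "control"), c(n1, n2)))
}

# Tiny synthetic cohort (records + maps) used across tests.
tinyCohort <- function(grid = c(8, 8, 8), tt = 40, groups = c(4, 4, 4),
                       regions = list(), seed = 11, ...) {
    generateCohort(syntheticConfig(gridShape = grid, nTimepoints = tt,
                                   groupSizes = groups,
                                   effectRegions = regions,
                                   seed = seed, ...))
}
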