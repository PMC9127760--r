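#' Gaussian-process classifier with a linear kernel
#'
#' Laplace-approximate Gaussian-process classification with a softmax
#' (multinomial logistic) likelihood and kernel k(x, x') = x'x + b,
#' where b is the variance of an implicit intercept process. Binary
#' classification is the two-class case of the same model. The Newton
#' iteration on the latent values is deterministic; at the posterior
#' mode the latent function is linear in the features, so the model
#' exposes an exact per-class weight vector w_c = X'(y_c - pi_c) and
#' intercept w0_c = b * sum(y_c - pi_c), giving the voxel-space
#' discriminative pattern directly.
#'
#' @param x subjects x features matrix.
#' @param y labels (2 classes for "binary"; >= 3 allowed for
#'   "multiclass", and 2 degrade gracefully to binary behavior).
#' @param mode "binary" or "multiclass".
#' @param biasVariance prior variance b of the intercept process.
#' @param positiveClass positive label for binary use (first weight
#'   column orientation); defaults to the alphabetically first.
#' @param maxIter,tol Newton iteration cap and convergence tolerance on
#'   the latent values.
#' @return a [LinearModel-class] object with one weight column per
#'   class.
#' @references Rasmussen & Williams (2006), Gaussian Processes for
#'   Machine Learning, ch. 3.
#' @export
fitGPC <- function(x, y, mode = c("binary", "multiclass"),
                   biasVariance = 1, positiveClass = NULL,
                   maxIter = 200L, tol = 1e-6) {
    mode <- match.arg(mode)
    x <- as.matrix(x)
    y <- as.character(y)
    cls <- sort(unique(y))
    nc <- length(cls)
    if (mode == "binary" && nc != 2L)
        stop("fitGPC: binary mode requires exactly 2 classes")
    if (mode == "multiclass" && nc < 2L)
        stop("fitGPC: need at least 2 classes")
    positiveClass <- positiveClass %||% cls[1]
    n <- nrow(x)

    kmat <- tcrossprod(x) + biasVariance
    jitter <- 1e-8 * (mean(diag(kmat)) + 1)
    kmat <- kmat + diag(jitter, n)
    kinv <- chol2inv(chol(kmat))

    yMat <- outer(y, cls, `==`) * 1            # n x C one-hot
    f <- matrix(0, n, nc)
    iter <- 0L
    repeat {
        iter <- iter + 1L
        p <- softmaxRows(f)
        grad <- yMat - p                        # d loglik / d f
        w <- softmaxHessian(p)                  # nC x nC, positive semidef
        a <- blockDiag(kinv, nc) + w
        rhs <- as.vector(w %*% as.vector(f)) + as.vector(grad)
        fNew <- matrix(solve(a, rhs), n, nc)
        delta <- max(abs(fNew - f))
        f <- fNew
        if (delta < tol) break
        if (iter >= maxIter)
            stop("fitGPC: Newton iterations did not converge (",
                 iter, " iterations, last step ", signif(delta, 3), ")")
    }
    p <- softmaxRows(f)
    alpha <- yMat - p                           # dual coefficients
    weights <- crossprod(x, alpha)              # features x classes
    bias <- biasVariance * colSums(alpha)
    ord <- if (nc == 2L) match(c(positiveClass,
                                 setdiff(cls, positiveClass)), cls)
           else seq_len(nc)
    new("LinearModel", weights = weights[, ord, drop = FALSE],
        bias = bias[ord], classes = cls[ord],
        algorithm = if (mode == "binary") "bgpc" else "mgpc",
        fit = list(alpha = alpha[, ord, drop = FALSE], iterations = iter,
                   biasVariance = biasVariance, mode = mode))
}

#' Class probabilities from a fitted GPC
#'
#' Softmax of the posterior-mode latent means at the query points
#' (deterministic plug-in predictor). Probabilities sum to 1 by
#' construction.
#'
#' @param model a [LinearModel-class] from [fitGPC()].
#' @param x query subjects x features matrix.
#' @return matrix of class probabilities (columns named by class).
#' @export
predictGPC <- function(model, x) {
    f <- sweep(as.matrix(x) %*% model@weights, 2L, model@bias, `+`)
    p <- softmaxRows(f)
    colnames(p) <- model@classes
    p
}

softmaxRows <- function(f) {
    f <- f - apply(f, 1L, max)
    e <- exp(f)
    e / rowSums(e)
}

# Hessian of the negative softmax log-likelihood in the stacked
# (class-major) latent space: W = diag(pi) - Pi Pi', block structure
# over classes.
softmaxHessian <- function(p) {
    n <- nrow(p); nc <- ncol(p)
    w <- matrix(0, n * nc, n * nc)
    for (c1 in seq_len(nc)) for (c2 in seq_len(nc)) {
        idx1 <- (c1 - 1L) * n + seq_len(n)
        idx2 <- (c2 - 1L) * n + seq_len(n)
        block <- -p[, c1] * p[, c2]
        if (c1 == c2) block <- block + p[, c1]
        w[cbind(idx1, idx2)] <- block
    }
    w
}

blockDiag <- function(m, times) {
    n <- nrow(m)
    out <- matrix(0, n * times, n * times)
    for (b in seq_len(times)) {
        idx <- (b - 1L) * n + seq_len(n)
        out[idx, idx] <- m
    }
    out
}
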