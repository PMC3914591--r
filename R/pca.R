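# PCA of the training window covariance and window projection.

# Fix eigenvector signs (largest-magnitude entry positive, earliest index
# on ties) and order exactly-tied eigenvalues by the lexicographic order of
# their sign-fixed eigenvectors. Individual eigenvectors are unstable when
# eigenvalues coincide; the spanned subspace and all norms remain
# well-defined, and this convention at least makes the output reproducible
# across runs and solvers.
canonicalizeEigen <- function(values, vectors) {
    for (j in seq_len(ncol(vectors))) {
        i <- which.max(abs(vectors[, j]))
        if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
    }
    tol <- 1e-12 * max(abs(values), 1)
    j <- 1L
    while (j <= length(values)) {
        grp <- which(abs(values - values[j]) <= tol & seq_along(values) >= j)
        grp <- grp[grp <= (j + length(grp) - 1L)]  # contiguous run only
        if (length(grp) > 1L) {
            ord <- do.call(order,
                           as.data.frame(t(vectors[, grp, drop = FALSE])))
            vectors[, grp] <- vectors[, grp[ord], drop = FALSE]
        }
        j <- j + length(grp)
    }
    list(values = values, vectors = vectors)
}

#' Fit PCA on a training window matrix
#'
#' Computes the per-column mean of the training windows and the
#' eigendecomposition of their sample covariance matrix (the `l x l`
#' covariance route, not an SVD of the data matrix: `l` is small even
#' when the number of windows is large). Eigenvalues are sorted
#' non-increasing, with numerical negatives below `1e-10` in magnitude
#' clipped to zero; eigenvector signs are fixed so each column's
#' largest-magnitude entry is positive.
#'
#' @param training a [WindowMatrix-class] with at least 2 rows and no
#'   non-finite entries.
#' @return a [WindowPCA-class] model.
#' @examples
#' sigs <- list(Signal(rnorm(2048), 256, "A", "a"),
#'              Signal(rnorm(2048), 256, "B", "b"))
#' tm <- stackTrainingMatrix(sigs, 128, 1)
#' fit <- fitWindowPCA(tm)
#' explainedVarianceRatio(fit, 3)
#' @seealso [projectWindows()], [explainedVarianceRatio()]
#' @export
fitWindowPCA <- function(training) {
    stopifnot(is(training, "WindowMatrix"))
    X <- training@windowData
    if (nrow(X) < 2L)
        stop("PCA needs at least 2 training windows, got ", nrow(X),
             call. = FALSE)
    bad <- which(!apply(is.finite(X), 1L, all))
    if (length(bad))
        stop(sprintf(
            "non-finite entries in training window(s): %s",
            paste(sprintf("%s#%d", training@rowSources[bad],
                          training@rowWindows[bad])[seq_len(min(5, length(bad)))],
                  collapse = ", ")), call. = FALSE)
    mu <- colMeans(X)
    C <- stats::cov(X)
    e <- eigen(C, symmetric = TRUE)
    vals <- e$values
    vals[vals < 0 & vals > -1e-10] <- 0
    if (any(vals < 0))
        vals[vals < 0] <- 0  # larger negatives would signal a broken input
    ce <- canonicalizeEigen(vals, e$vectors)
    new("WindowPCA",
        trainingMean = mu,
        pcLoadings = ce$vectors,
        pcEigenvalues = ce$values,
        windowLength = training@windowLength,
        nTrainRows = nrow(X))
}

#' Project a single window onto the PC basis
#'
#' Subtracts the stored training mean and takes inner products with every
#' eigenvector: `score_v = <window - mean, V_v>`. Since the loadings form
#' a full orthonormal basis, the score vector preserves the centered
#' window's Euclidean norm and the window can be reconstructed exactly
#' from all `l` scores.
#'
#' @param model a [WindowPCA-class].
#' @param window numeric vector of length `windowLength(model)`.
#' @return numeric vector of `l` PC scores, in decreasing-eigenvalue
#'   order.
#' @seealso [projectWindows()] for whole matrices,
#'   [reconstructWindow()]
#' @export
projectWindow <- function(model, window) {
    stopifnot(is(model, "WindowPCA"))
    if (length(window) != model@windowLength)
        stop(sprintf(
            "window length %d does not match model window length %d",
            length(window), model@windowLength), call. = FALSE)
    as.numeric(crossprod(model@pcLoadings, window - model@trainingMean))
}

#' Project every row of a window matrix onto the PC basis
#'
#' @param model a [WindowPCA-class].
#' @param windows a [WindowMatrix-class] (any mode) with matching window
#'   length, or a numeric matrix with `l` columns.
#' @return numeric score matrix, one row of `l` scores per window.
#' @export
projectWindows <- function(model, windows) {
    stopifnot(is(model, "WindowPCA"))
    X <- if (is(windows, "WindowMatrix")) windows@windowData else
        as.matrix(windows)
    if (ncol(X) != model@windowLength)
        stop(sprintf(
            "window length %d does not match model window length %d",
            ncol(X), model@windowLength), call. = FALSE)
    sweep(X, 2L, model@trainingMean) %*% model@pcLoadings
}

#' Reconstruct a window from its PC scores
#'
#' Inverse of [projectWindow()]: `mean + sum_v score_v V_v`. With all `l`
#' scores the reconstruction is exact; with a truncated score vector
#' (remaining entries zero) it is the rank-limited approximation.
#'
#' @param model a [WindowPCA-class].
#' @param scores numeric vector of up to `l` PC scores (padded with zeros
#'   if shorter).
#' @return numeric vector of length `l`.
#' @export
reconstructWindow <- function(model, scores) {
    stopifnot(is(model, "WindowPCA"))
    l <- model@windowLength
    if (length(scores) > l)
        stop("more scores than model dimensions", call. = FALSE)
    s <- c(scores, rep(0, l - length(scores)))
    as.numeric(model@trainingMean + model@pcLoadings %*% s)
}

#' Fraction of variance explained by the leading components
#'
#' Ratio of the sum of the first `nComponents` eigenvalues to the sum of
#' all eigenvalues. For a degenerate model with zero total variance the
#' ratio is defined as 1.
#'
#' @param model a [WindowPCA-class].
#' @param nComponents number of leading components, `1 <= n <= l`.
#' @return a fraction in \[0, 1\], non-decreasing in `nComponents`.
#' @export
explainedVarianceRatio <- function(model, nComponents) {
    stopifnot(is(model, "WindowPCA"))
    l <- model@windowLength
    if (length(nComponents) != 1L || nComponents < 1 || nComponents > l ||
        nComponents != round(nComponents))
        stop(sprintf(
            "'nComponents' must be an integer in [1, %d], got %s",
            l, deparse(nComponents)), call. = FALSE)
    tot <- sum(model@pcEigenvalues)
    if (tot == 0) return(1)
    sum(model@pcEigenvalues[seq_len(nComponents)]) / tot
}
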