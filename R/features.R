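# Per-window feature schemes: FFPC and PCPEM.

asScoreMatrix <- function(scores) {
    if (is.matrix(scores)) scores else matrix(scores, nrow = 1L)
}

#' First-few-PCs (FFPC) feature vectors
#'
#' Retains the first `nComponents` PC scores of each window, in component
#' order. The default of 3 keeps the feature space directly plottable; in
#' practice dimensions beyond three have not improved window
#' classification for signals of this kind.
#'
#' @param scores a score vector for one window, or a score matrix (one
#'   row per window) as returned by [projectWindows()].
#' @param nComponents number of leading scores to keep,
#'   `1 <= n <= l` (default 3).
#' @return matrix with `nComponents` columns, one row per window (a
#'   single input vector yields a 1-row matrix).
#' @seealso [pcpemFeatures()], [windowFeatures()]
#' @export
ffpcFeatures <- function(scores, nComponents = 3L) {
    S <- asScoreMatrix(scores)
    l <- ncol(S)
    if (length(nComponents) != 1L || nComponents < 1 || nComponents > l ||
        nComponents != round(nComponents))
        stop(sprintf("'nComponents' must be an integer in [1, %d], got %s",
                     l, deparse(nComponents)), call. = FALSE)
    S[, seq_len(nComponents), drop = FALSE]
}

#' PC-space energy measure of a window
#'
#' Sum of squared PC scores `E(w) = sum_{v=1}^{t} score_v(w)^2` up to the
#' truncation `t`. With `t = l` (the full basis) this equals the squared
#' Euclidean norm of the mean-centered window (Parseval); in practice a
#' truncation of `floor(l / 2)` captures the discriminative energy, which
#' is the default used by [pcpemFeatures()]. Invariant to the eigenvector
#' sign convention.
#'
#' @param scores score vector or matrix as in [ffpcFeatures()].
#' @param truncation number of leading scores summed, `1 <= t <= l`;
#'   default `floor(l / 2)`.
#' @return nonnegative numeric vector, one energy per window.
#' @export
energyMeasure <- function(scores, truncation = NULL) {
    S <- asScoreMatrix(scores)
    l <- ncol(S)
    if (is.null(truncation)) truncation <- max(1L, l %/% 2L)
    if (length(truncation) != 1L || truncation < 1 || truncation > l ||
        truncation != round(truncation))
        stop(sprintf("'truncation' must be an integer in [1, %d], got %s",
                     l, deparse(truncation)), call. = FALSE)
    rowSums(S[, seq_len(truncation), drop = FALSE]^2)
}

#' First-few-PCs plus energy (PCPEM) feature vectors
#'
#' Concatenates the first `nPcs` PC scores with the PC-space energy
#' measure, giving a `nPcs + 1`-dimensional vector. The default
#' (`nPcs = 2`, so a 3-dimensional vector) replaces the third PC score of
#' FFPC with the window energy, which greatly improves separability when
#' classes differ in signal power (ictal activity typically carries much
#' higher energy than non-ictal activity).
#'
#' @param scores score vector or matrix as in [ffpcFeatures()].
#' @param nPcs number of leading scores kept (default 2).
#' @param truncation energy truncation, passed to [energyMeasure()]
#'   (default `floor(l / 2)`).
#' @return matrix with `nPcs + 1` columns; the last column is the energy.
#' @export
pcpemFeatures <- function(scores, nPcs = 2L, truncation = NULL) {
    S <- asScoreMatrix(scores)
    cbind(ffpcFeatures(S, nPcs), energyMeasure(S, truncation))
}

#' Compute a labeled FeatureSet for a window matrix under one scheme
#'
#' Projects every window of `windows` with `model` and applies the chosen
#' feature scheme, carrying each window's label, source and index into
#' the result. `"EM"` is a 1-dimensional energy-only control scheme,
#' useful for showing when spectral structure (FFPC) rather than power
#' separates classes.
#'
#' @param model a [WindowPCA-class].
#' @param windows a [WindowMatrix-class] with matching window length.
#' @param scheme `"FFPC"`, `"PCPEM"` or `"EM"`.
#' @param nComponents FFPC dimension (default 3).
#' @param nPcs PCPEM leading-score count (default 2).
#' @param truncation energy truncation (default `floor(l / 2)`).
#' @return a [FeatureSet-class].
#' @examples
#' sigs <- list(Signal(rnorm(2048), 256, "A", "a"),
#'              Signal(5 * rnorm(2048), 256, "B", "b"))
#' tm <- stackTrainingMatrix(sigs, 256, 1)
#' fit <- fitWindowPCA(tm)
#' windowFeatures(fit, tm, "PCPEM")
#' @export
windowFeatures <- function(model, windows, scheme = c("FFPC", "PCPEM", "EM"),
                           nComponents = 3L, nPcs = 2L, truncation = NULL) {
    scheme <- match.arg(scheme)
    stopifnot(is(windows, "WindowMatrix"))
    S <- projectWindows(model, windows)
    vals <- switch(scheme,
        FFPC = ffpcFeatures(S, nComponents),
        PCPEM = pcpemFeatures(S, nPcs, truncation),
        EM = matrix(energyMeasure(S, truncation), ncol = 1L))
    new("FeatureSet",
        featureValues = vals,
        featureScheme = scheme,
        rowLabels = windows@rowLabels,
        rowSources = windows@rowSources,
        rowWindows = windows@rowWindows)
}
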