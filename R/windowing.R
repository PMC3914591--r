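# Window embeddings: signals -> windows-as-rows matrices.

checkWindowLength <- function(windowLength, n) {
    if (length(windowLength) != 1L || !is.finite(windowLength) ||
        windowLength != round(windowLength) || windowLength < 1L)
        stop("'windowLength' must be a positive integer, got ",
             deparse(windowLength), call. = FALSE)
    if (windowLength > n)
        stop(sprintf(
            "window length %d exceeds signal length %d", windowLength, n),
            call. = FALSE)
    as.integer(windowLength)
}

#' Embed a signal as non-overlapping windows
#'
#' Partitions the signal into `m = floor(N / l)` consecutive disjoint
#' blocks of length `l`; block `w` holds samples `(w-1)l + 1 .. wl` in
#' original order and becomes row `w` of the matrix. When `l` does not
#' divide `N`, the trailing `N mod l` samples are discarded with a
#' warning. Treating each block as one multivariate observation keeps
#' window-to-window autocorrelation far lower than the classical
#' overlapping (trajectory-matrix) embedding, which is the point of the
#' method: PCA assumes weakly dependent observations.
#'
#' @param signal a [Signal-class].
#' @param windowLength window length `l` in samples, `1 <= l <= N`.
#' @return a [WindowMatrix-class] in `"nonoverlapping"` mode with
#'   `floor(N / l)` rows; row labels/sources are inherited from the
#'   signal, window indices start at 1.
#' @examples
#' sig <- Signal(seq_len(4096), 173.61, classLabel = "A")
#' dim(embedNonoverlapping(sig, 512))   # 8 x 512
#' @seealso [embedOverlapping()], [stackTrainingMatrix()]
#' @export
embedNonoverlapping <- function(signal, windowLength) {
    stopifnot(is(signal, "Signal"))
    x <- signal@samples
    n <- length(x)
    l <- checkWindowLength(windowLength, n)
    m <- n %/% l
    if (n %% l != 0L)
        warning(sprintf(
            "discarding trailing %d of %d samples from '%s' (window length %d)",
            n %% l, n, signal@sourceId, l), call. = FALSE)
    mat <- matrix(x[seq_len(m * l)], nrow = m, ncol = l, byrow = TRUE)
    new("WindowMatrix",
        windowData = mat,
        windowLength = l,
        rowLabels = rep(signal@classLabel, m),
        rowSources = rep(signal@sourceId, m),
        rowWindows = seq_len(m),
        embeddingMode = "nonoverlapping")
}

#' Embed a signal as overlapping (trajectory-matrix) windows
#'
#' The classical Hankel embedding used in singular spectrum analysis: row
#' `j` holds samples `j .. j + l - 1`, giving `N - l + 1` rows whose
#' adjacent rows agree on `l - 1` shifted entries. Provided for
#' comparison studies of window redundancy; the non-overlapping embedding
#' is what the feature pipeline uses.
#'
#' @inheritParams embedNonoverlapping
#' @return a [WindowMatrix-class] in `"overlapping"` mode with
#'   `N - l + 1` rows.
#' @examples
#' sig <- Signal(1:5, 1)
#' windowData(embedOverlapping(sig, 3))  # rows 123, 234, 345
#' @export
embedOverlapping <- function(signal, windowLength) {
    stopifnot(is(signal, "Signal"))
    x <- signal@samples
    n <- length(x)
    l <- checkWindowLength(windowLength, n)
    m <- n - l + 1L
    idx <- outer(seq_len(m) - 1L, seq_len(l), `+`)
    mat <- matrix(x[idx], nrow = m, ncol = l)
    new("WindowMatrix",
        windowData = mat,
        windowLength = l,
        rowLabels = rep(signal@classLabel, m),
        rowSources = rep(signal@sourceId, m),
        rowWindows = seq_len(m),
        embeddingMode = "overlapping")
}

#' Stack labeled signals into a shuffled training matrix
#'
#' Embeds each signal with non-overlapping windows, concatenates the
#' rows, and randomly permutes the row order so consecutive windows of
#' one signal are not adjacent in the training matrix (a random
#' allocation of data segments; with few long signals per group a random
#' allocation of whole signals is unrealistic, so it is the windows that
#' are shuffled). The permutation is reproducible from `shuffleSeed`.
#'
#' @param signals list of labeled [Signal-class] objects carrying at
#'   least two distinct class labels; each must be at least
#'   `windowLength` samples long.
#' @param windowLength window length `l`.
#' @param shuffleSeed integer seed for the row permutation.
#' @return a [WindowMatrix-class] in `"nonoverlapping"` mode with
#'   `sum_i floor(N_i / l)` rows, labels and origins carried per row.
#' @examples
#' sigs <- list(Signal(rnorm(1024), 256, "A", "a1"),
#'              Signal(rnorm(1024), 256, "B", "b1"))
#' tm <- stackTrainingMatrix(sigs, 256, shuffleSeed = 1)
#' table(rowLabels(tm))
#' @export
stackTrainingMatrix <- function(signals, windowLength, shuffleSeed = 1L) {
    stopifnot(is.list(signals), length(signals) >= 1L,
              all(vapply(signals, is, logical(1), class2 = "Signal")))
    labs <- vapply(signals, function(s) s@classLabel, character(1))
    if (length(unique(labs[!is.na(labs)])) < 2L)
        stop("classification requires >= 2 groups", call. = FALSE)
    parts <- lapply(signals, embedNonoverlapping, windowLength = windowLength)
    mat <- do.call(rbind, lapply(parts, function(p) p@windowData))
    rl <- unlist(lapply(parts, function(p) p@rowLabels))
    rs <- unlist(lapply(parts, function(p) p@rowSources))
    rw <- unlist(lapply(parts, function(p) p@rowWindows))
    set.seed(as.integer(shuffleSeed))
    perm <- sample.int(nrow(mat))
    new("WindowMatrix",
        windowData = mat[perm, , drop = FALSE],
        windowLength = as.integer(windowLength),
        rowLabels = rl[perm],
        rowSources = rs[perm],
        rowWindows = as.integer(rw[perm]),
        embeddingMode = "nonoverlapping")
}
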