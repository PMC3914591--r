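# 1-NN classification and cross-validated accuracy.

# Squared Euclidean distances, queries x references.
pairwiseSqDist <- function(Q, R) {
    d2 <- matrix(rowSums(Q^2), nrow(Q), nrow(R)) +
        matrix(rowSums(R^2), nrow(Q), nrow(R), byrow = TRUE) -
        2 * tcrossprod(Q, R)
    d2[d2 < 0] <- 0
    d2
}

predict1NNMatrix <- function(trainValues, trainLabels, queryValues) {
    d2 <- pairwiseSqDist(queryValues, trainValues)
    # which.min returns the earliest index on ties: the documented
    # deterministic tie-break (smallest training-set index).
    trainLabels[apply(d2, 1L, which.min)]
}

#' One-nearest-neighbour prediction
#'
#' Assigns each query the label of the training vector at smallest
#' Euclidean distance. Exact ties are broken deterministically in favour
#' of the smallest training-set index. The classifier is deliberately
#' parameter-free: the burden of separation rests on the feature
#' extraction, not on the classifier.
#'
#' @param train a labeled [FeatureSet-class] (no `NA` labels).
#' @param query a numeric vector (one feature vector), a numeric matrix
#'   (one row per query), or a [FeatureSet-class] of the same scheme and
#'   dimension.
#' @return character vector of predicted labels, one per query.
#' @examples
#' fs <- new("FeatureSet",
#'           featureValues = rbind(c(0, 0, 0), c(10, 10, 10)),
#'           featureScheme = "FFPC", rowLabels = c("A", "B"),
#'           rowSources = c("a", "b"), rowWindows = c(1L, 1L))
#' predict1NN(fs, c(1, 0, 0))   # "A"
#' @export
predict1NN <- function(train, query) {
    stopifnot(is(train, "FeatureSet"))
    if (nrow(train@featureValues) < 1L)
        stop("empty training set", call. = FALSE)
    if (anyNA(train@rowLabels))
        stop("training features must all be labeled", call. = FALSE)
    Q <- if (is(query, "FeatureSet")) {
        if (query@featureScheme != train@featureScheme)
            stop(sprintf("scheme mismatch: train is %s, query is %s",
                         train@featureScheme, query@featureScheme),
                 call. = FALSE)
        query@featureValues
    } else if (is.matrix(query)) query else matrix(query, nrow = 1L)
    if (ncol(Q) != ncol(train@featureValues))
        stop(sprintf("query dimension %d does not match training dimension %d",
                     ncol(Q), ncol(train@featureValues)), call. = FALSE)
    predict1NNMatrix(train@featureValues, train@rowLabels, Q)
}

# Stratified fold assignment: within each label, a seeded random
# permutation is dealt round-robin into folds 1..k, keeping per-fold label
# proportions within one window of the global proportions.
makeStratifiedFolds <- function(labels, k, seed) {
    if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
    tab <- table(labels)
    if (any(tab < k))
        stop(sprintf(
            "label '%s' has only %d windows, fewer than k = %d folds; use a smaller k",
            names(tab)[which.min(tab)], min(tab), k), call. = FALSE)
    set.seed(as.integer(seed))
    fold <- integer(length(labels))
    for (lv in names(tab)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

standardizeTrainTest <- function(train, test) {
    mu <- colMeans(train)
    sdv <- apply(train, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    list(train = scale(train, center = mu, scale = sdv),
         test = scale(test, center = mu, scale = sdv))
}

buildCVReport <- function(foldAcc, segAcc, confusion, config) {
    labs <- sort(names(confusion$correct))
    new("CVReport",
        foldAccuracies = foldAcc,
        meanAccuracy = mean(foldAcc),
        sdAccuracy = stats::sd(foldAcc),
        foldSegmentAccuracies = segAcc,
        confusionTotals = data.frame(
            label = labs,
            correct = as.integer(confusion$correct[labs]),
            incorrect = as.integer(confusion$incorrect[labs]),
            stringsAsFactors = FALSE),
        configEcho = config)
}

accumulateConfusion <- function(confusion, truth, pred) {
    for (lv in unique(truth)) {
        hit <- sum(truth == lv & pred == lv)
        miss <- sum(truth == lv) - hit
        confusion$correct[lv] <- sum(confusion$correct[lv], hit, na.rm = TRUE)
        confusion$incorrect[lv] <- sum(confusion$incorrect[lv], miss,
                                       na.rm = TRUE)
    }
    confusion
}

segmentMajorityAccuracy <- function(truth, pred, sources) {
    segs <- unique(sources)
    ok <- vapply(segs, function(sg) {
        sel <- sources == sg
        tab <- sort(table(pred[sel]), decreasing = TRUE)
        # alphabetically-first label wins exact vote ties (deterministic)
        winners <- names(tab)[tab == tab[1L]]
        min(winners) == truth[sel][1L]
    }, logical(1))
    mean(ok)
}

newConfusion <- function(labels) {
    labs <- sort(unique(labels))
    list(correct = stats::setNames(rep(0L, length(labs)), labs),
         incorrect = stats::setNames(rep(0L, length(labs)), labs))
}

#' Stratified k-fold cross-validated 1-NN accuracy of a feature set
#'
#' Randomly partitions the windows into `k` label-stratified folds using
#' `seed`; for each fold a 1-NN classifier is built from the other
#' `k - 1` folds (with optional per-dimension z-scoring whose mean/sd are
#' computed from the training folds only) and window accuracy is measured
#' on the held-out fold. Accuracy is the pooled fraction of test windows
#' of all classes that are correctly labeled.
#'
#' Note that features here are taken as given; when features derive from
#' a PCA model, fitting that model inside each fold is the leakage-free
#' protocol — use [evaluatePipeline()] for that.
#'
#' @param features a labeled [FeatureSet-class]; every label needs at
#'   least `k` windows.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param standardize z-score features per dimension using training-fold
#'   statistics. Default `NULL` resolves to `TRUE` for PCPEM (whose
#'   energy coordinate is on a squared-amplitude scale that would
#'   otherwise dominate Euclidean distance) and `FALSE` otherwise.
#' @return a [CVReport-class].
#' @export
kfoldAccuracy <- function(features, k = 10L, seed = 1L, standardize = NULL) {
    stopifnot(is(features, "FeatureSet"))
    if (is.null(standardize)) standardize <- features@featureScheme == "PCPEM"
    labels <- features@rowLabels
    if (anyNA(labels)) stop("all windows must be labeled", call. = FALSE)
    if (length(unique(labels)) < 2L)
        stop("classification requires >= 2 groups", call. = FALSE)
    k <- as.integer(k)
    fold <- makeStratifiedFolds(labels, k, seed)
    X <- features@featureValues
    foldAcc <- segAcc <- numeric(k)
    confusion <- newConfusion(labels)
    for (f in seq_len(k)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[!tr, , drop = FALSE]
        if (standardize) {
            z <- standardizeTrainTest(Xtr, Xte)
            Xtr <- z$train; Xte <- z$test
        }
        pred <- predict1NNMatrix(Xtr, labels[tr], Xte)
        truth <- labels[!tr]
        foldAcc[f] <- mean(pred == truth)
        segAcc[f] <- segmentMajorityAccuracy(truth, pred,
                                             features@rowSources[!tr])
        confusion <- accumulateConfusion(confusion, truth, pred)
    }
    buildCVReport(foldAcc, segAcc, confusion, list(
        window_length = NA_integer_,
        scheme = features@featureScheme,
        d = ncol(X), k = k, seed = as.integer(seed),
        standardize = standardize))
}

#' End-to-end cross-validated evaluation of the window-PCA pipeline
#'
#' Embeds every signal with non-overlapping windows, then runs stratified
#' k-fold cross-validation over the pooled windows where, within each
#' fold, the PCA model is fitted on the training-fold windows only;
#' features of training and test windows are both derived from that
#' model, optional standardization statistics come from the training
#' features only, and 1-NN accuracy is measured on the held-out windows.
#' Refitting PCA per fold keeps held-out windows out of the basis
#' estimation entirely.
#'
#' @param signals list of labeled [Signal-class] objects (>= 2 distinct
#'   labels).
#' @param windowLength window length `l`.
#' @param scheme `"FFPC"`, `"PCPEM"` or `"EM"` (energy-only control).
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param nComponents,nPcs,truncation scheme parameters, as in
#'   [windowFeatures()].
#' @param standardize as in [kfoldAccuracy()].
#' @return a [CVReport-class] whose `configEcho` records every parameter.
#' @examples
#' ds <- freiburgLikePreset(nSignalsPerClass = 4, signalLength = 4096,
#'                          seed = 1)
#' sigs <- generateDataset(ds)
#' evaluatePipeline(sigs, windowLength = 512, scheme = "FFPC", k = 4,
#'                  seed = 1)
#' @export
evaluatePipeline <- function(signals, windowLength,
                             scheme = c("FFPC", "PCPEM", "EM"),
                             k = 10L, seed = 1L,
                             nComponents = 3L, nPcs = 2L, truncation = NULL,
                             standardize = NULL) {
    scheme <- match.arg(scheme)
    if (is.null(standardize)) standardize <- scheme == "PCPEM"
    stopifnot(is.list(signals),
              all(vapply(signals, is, logical(1), class2 = "Signal")))
    labs <- vapply(signals, function(s) s@classLabel, character(1))
    if (anyNA(labs) || length(unique(labs)) < 2L)
        stop("classification requires >= 2 groups", call. = FALSE)
    parts <- lapply(signals, embedNonoverlapping, windowLength = windowLength)
    X <- do.call(rbind, lapply(parts, function(p) p@windowData))
    rl <- unlist(lapply(parts, function(p) p@rowLabels))
    rs <- unlist(lapply(parts, function(p) p@rowSources))
    rw <- unlist(lapply(parts, function(p) p@rowWindows))
    l <- as.integer(windowLength)
    k <- as.integer(k)
    fold <- makeStratifiedFolds(rl, k, seed)
    foldAcc <- segAcc <- numeric(k)
    confusion <- newConfusion(rl)
    for (f in seq_len(k)) {
        tr <- fold != f
        wmTr <- new("WindowMatrix", windowData = X[tr, , drop = FALSE],
                    windowLength = l, rowLabels = rl[tr],
                    rowSources = rs[tr], rowWindows = rw[tr],
                    embeddingMode = "nonoverlapping")
        wmTe <- new("WindowMatrix", windowData = X[!tr, , drop = FALSE],
                    windowLength = l, rowLabels = rl[!tr],
                    rowSources = rs[!tr], rowWindows = rw[!tr],
                    embeddingMode = "nonoverlapping")
        model <- fitWindowPCA(wmTr)
        ftr <- windowFeatures(model, wmTr, scheme, nComponents, nPcs,
                              truncation)
        fte <- windowFeatures(model, wmTe, scheme, nComponents, nPcs,
                              truncation)
        Xtr <- ftr@featureValues
        Xte <- fte@featureValues
        if (standardize) {
            z <- standardizeTrainTest(Xtr, Xte)
            Xtr <- z$train; Xte <- z$test
        }
        pred <- predict1NNMatrix(Xtr, rl[tr], Xte)
        truth <- rl[!tr]
        foldAcc[f] <- mean(pred == truth)
        segAcc[f] <- segmentMajorityAccuracy(truth, pred, rs[!tr])
        confusion <- accumulateConfusion(confusion, truth, pred)
    }
    d <- switch(scheme, FFPC = nComponents, PCPEM = nPcs + 1L, EM = 1L)
    buildCVReport(foldAcc, segAcc, confusion, list(
        window_length = l,
        scheme = scheme,
        d = as.integer(d),
        k = k,
        seed = as.integer(seed),
        standardize = standardize,
        n_components = as.integer(nComponents),
        n_pcs = as.integer(nPcs),
        energy_truncation = as.integer(
            if (is.null(truncation)) max(1L, l %/% 2L) else truncation),
        n_windows = nrow(X),
        n_signals = length(signals)))
}
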