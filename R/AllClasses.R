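#' @import methods
NULL

#' Signal: a labeled, uniformly sampled one-dimensional signal
#'
#' Container for a single-channel discretely sampled signal. Multichannel
#' records are represented as one `Signal` per channel; the windowing and
#' feature-extraction machinery is strictly single-channel.
#'
#' @slot samples numeric vector of amplitudes (arbitrary units, e.g. uV).
#' @slot sampleRate sampling rate in samples/second; carried as metadata
#'   (the embedding and PCA are index-based) and used for axis labels and
#'   for the synthetic generator.
#' @slot classLabel class identifier, or `NA_character_` when unlabeled.
#' @slot sourceId free-text provenance (file name, channel, hour).
#'
#' @seealso [Signal()] for the constructor, [embedNonoverlapping()].
#' @exportClass Signal
setClass("Signal",
    representation(
        samples = "numeric",
        sampleRate = "numeric",
        classLabel = "character",
        sourceId = "character"
    )
)

setValidity("Signal", function(object) {
    msg <- character()
    if (length(object@samples) < 1L)
        msg <- c(msg, "'samples' must contain at least one value")
    if (!all(is.finite(object@samples)))
        msg <- c(msg, "'samples' must all be finite")
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
        msg <- c(msg, "'sampleRate' must be a single positive number")
    if (length(object@classLabel) != 1L)
        msg <- c(msg, "'classLabel' must be a single string (or NA)")
    if (length(object@sourceId) != 1L)
        msg <- c(msg, "'sourceId' must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct a Signal
#'
#' @param samples numeric vector of finite amplitudes, length >= 1.
#' @param sampleRate sampling rate in Hz (> 0).
#' @param classLabel class identifier (any string) or `NA` for an
#'   unlabeled signal.
#' @param sourceId provenance string; defaults to `"signal"`.
#' @return a [Signal-class] object.
#' @examples
#' sig <- Signal(sin(2 * pi * 10 * (0:999) / 250), sampleRate = 250,
#'               classLabel = "A", sourceId = "demo")
#' sig
#' @export
Signal <- function(samples, sampleRate, classLabel = NA, sourceId = "signal") {
    new("Signal",
        samples = as.numeric(samples),
        sampleRate = as.numeric(sampleRate),
        classLabel = as.character(classLabel),
        sourceId = as.character(sourceId))
}

#' WindowMatrix: windows-as-rows embedding of one or more signals
#'
#' Each row is one length-`l` window of some source signal. In
#' `"nonoverlapping"` mode, rows originating from one signal cover disjoint
#' sample ranges `[(w-1)l + 1, wl]`; in `"overlapping"` mode row `j` holds
#' samples `j .. j+l-1` (the Hankel/trajectory embedding, provided for
#' comparison studies of the window-redundancy argument).
#'
#' @slot windowData numeric matrix, one row per window, `windowLength`
#'   columns.
#' @slot windowLength window length `l` in samples.
#' @slot rowLabels class label per row (`NA_character_` when unlabeled).
#' @slot rowSources source identifier per row.
#' @slot rowWindows 1-based window index `w` per row within its source.
#' @slot embeddingMode `"nonoverlapping"` or `"overlapping"`.
#'
#' @seealso [embedNonoverlapping()], [embedOverlapping()],
#'   [stackTrainingMatrix()].
#' @exportClass WindowMatrix
setClass("WindowMatrix",
    representation(
        windowData = "matrix",
        windowLength = "integer",
        rowLabels = "character",
        rowSources = "character",
        rowWindows = "integer",
        embeddingMode = "character"
    )
)

setValidity("WindowMatrix", function(object) {
    msg <- character()
    m <- nrow(object@windowData)
    if (m < 1L)
        msg <- c(msg, "window matrix must have at least one row")
    if (ncol(object@windowData) != object@windowLength)
        msg <- c(msg, sprintf("window matrix has %d columns but windowLength is %d",
                              ncol(object@windowData), object@windowLength))
    for (s in c("rowLabels", "rowSources", "rowWindows"))
        if (length(slot(object, s)) != m)
            msg <- c(msg, sprintf("'%s' must have one entry per row", s))
    if (!object@embeddingMode %in% c("nonoverlapping", "overlapping"))
        msg <- c(msg, "embeddingMode must be 'nonoverlapping' or 'overlapping'")
    if (length(msg)) msg else TRUE
})

#' WindowPCA: principal component model of a training window matrix
#'
#' Stores the column means, eigenvectors and eigenvalues of the sample
#' covariance of a (mean-centered) training [WindowMatrix-class]. The
#' loadings form a full orthonormal basis of the window space; eigenvector
#' signs are fixed so the largest-magnitude entry of each column is
#' positive (earliest index on ties), making the decomposition
#' reproducible across eigen-solvers.
#'
#' @slot trainingMean length-`l` vector of per-column training means.
#' @slot pcLoadings `l x l` orthonormal matrix; column `v` is eigenvector
#'   `V_v`, ordered by decreasing eigenvalue.
#' @slot pcEigenvalues length-`l` non-increasing nonnegative eigenvalues
#'   (tiny negative round-off is clipped to 0).
#' @slot windowLength window length `l`.
#' @slot nTrainRows number of training windows used in the fit.
#'
#' @seealso [fitWindowPCA()], [projectWindows()].
#' @exportClass WindowPCA
setClass("WindowPCA",
    representation(
        trainingMean = "numeric",
        pcLoadings = "matrix",
        pcEigenvalues = "numeric",
        windowLength = "integer",
        nTrainRows = "integer"
    )
)

setValidity("WindowPCA", function(object) {
    msg <- character()
    l <- object@windowLength
    if (length(object@trainingMean) != l)
        msg <- c(msg, "trainingMean length must equal windowLength")
    if (!all(dim(object@pcLoadings) == c(l, l)))
        msg <- c(msg, "pcLoadings must be windowLength x windowLength")
    if (length(object@pcEigenvalues) != l)
        msg <- c(msg, "pcEigenvalues length must equal windowLength")
    if (any(diff(object@pcEigenvalues) > 1e-10))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@pcEigenvalues < 0))
        msg <- c(msg, "eigenvalues must be nonnegative")
    gram <- crossprod(object@pcLoadings)
    if (max(abs(gram - diag(l))) > 1e-8)
        msg <- c(msg, "loadings are not orthonormal within 1e-8")
    if (length(msg)) msg else TRUE
})

#' FeatureSet: labeled per-window feature vectors under one scheme
#'
#' Rows of `featureValues` are per-window feature vectors, all produced by
#' the same scheme. The scheme is recorded so that FFPC and PCPEM vectors
#' are never mixed in a single classifier.
#'
#' @slot featureValues numeric matrix, one row per window, `d` columns.
#' @slot featureScheme one of `"FFPC"`, `"PCPEM"`, `"EM"` (energy-only
#'   1-D control scheme).
#' @slot rowLabels class label per row (may be `NA` for unlabeled windows).
#' @slot rowSources source identifier per row.
#' @slot rowWindows window index per row.
#'
#' @seealso [windowFeatures()], [kfoldAccuracy()], [predict1NN()].
#' @exportClass FeatureSet
setClass("FeatureSet",
    representation(
        featureValues = "matrix",
        featureScheme = "character",
        rowLabels = "character",
        rowSources = "character",
        rowWindows = "integer"
    )
)

setValidity("FeatureSet", function(object) {
    msg <- character()
    n <- nrow(object@featureValues)
    if (ncol(object@featureValues) < 1L)
        msg <- c(msg, "feature dimension must be >= 1")
    if (!all(is.finite(object@featureValues)))
        msg <- c(msg, "feature values must all be finite")
    if (!object@featureScheme %in% c("FFPC", "PCPEM", "EM"))
        msg <- c(msg, "featureScheme must be 'FFPC', 'PCPEM' or 'EM'")
    for (s in c("rowLabels", "rowSources", "rowWindows"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("'%s' must have one entry per row", s))
    if (length(msg)) msg else TRUE
})

#' CVReport: cross-validated classification accuracy report
#'
#' Per-fold and aggregated 1-NN accuracy from stratified k-fold
#' cross-validation, plus per-label confusion totals and a full echo of
#' the configuration (window length, scheme, dimension, k, seed,
#' standardization flag) so one report fully documents one run.
#'
#' The primary accuracy unit is the window. A secondary per-segment
#' accuracy (majority vote over each source signal's test windows) is also
#' recorded in `foldSegmentAccuracies`.
#'
#' @slot foldAccuracies per-fold window-level accuracy, fractions in
#'   \[0, 1\].
#' @slot meanAccuracy mean of `foldAccuracies`.
#' @slot sdAccuracy standard deviation of `foldAccuracies`.
#' @slot foldSegmentAccuracies per-fold majority-vote accuracy over
#'   source segments (secondary metric).
#' @slot confusionTotals data.frame with columns `label`, `correct`,
#'   `incorrect`, summed over folds.
#' @slot configEcho named list echoing the run configuration.
#'
#' @seealso [kfoldAccuracy()], [evaluatePipeline()], [writeCVReportJSON()].
#' @exportClass CVReport
setClass("CVReport",
    representation(
        foldAccuracies = "numeric",
        meanAccuracy = "numeric",
        sdAccuracy = "numeric",
        foldSegmentAccuracies = "numeric",
        confusionTotals = "data.frame",
        configEcho = "list"
    )
)

setValidity("CVReport", function(object) {
    msg <- character()
    k <- length(object@foldAccuracies)
    if (k < 2L)
        msg <- c(msg, "a report needs at least 2 folds")
    if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
        msg <- c(msg, "fold accuracies must lie in [0, 1]")
    if (abs(object@meanAccuracy - mean(object@foldAccuracies)) > 1e-12)
        msg <- c(msg, "meanAccuracy must equal mean(foldAccuracies)")
    if (abs(object@sdAccuracy - stats::sd(object@foldAccuracies)) > 1e-12)
        msg <- c(msg, "sdAccuracy must equal sd(foldAccuracies)")
    if (length(msg)) msg else TRUE
})

#' ClassSpec: parameters of one synthetic signal class
#'
#' Describes one class of the synthetic generator: a second-order
#' autoregressive resonance (a stationary process with a single tunable
#' spectral peak) with multiplicative gain, plus Poisson-placed
#' raised-cosine spike transients and additive white noise.
#'
#' @slot classLabel class identifier.
#' @slot centerFrequency resonance center frequency in Hz (must lie below
#'   the Nyquist frequency of the target sampling rate).
#' @slot bandwidth resonance half-power bandwidth in Hz; smaller values
#'   give a sharper spectral peak (pole radius `exp(-pi * bw / fs)`).
#' @slot amplitudeScale multiplicative gain applied to the unit-driven
#'   AR(2) output (> 0 unless the class is pure noise/spikes).
#' @slot spikeRate expected spike transients per second (>= 0).
#' @slot spikeAmplitude peak amplitude of each 50 ms raised-cosine spike.
#' @slot noiseSd standard deviation of additive white measurement noise.
#'
#' @seealso [classSpec()], [generateSignal()].
#' @exportClass ClassSpec
setClass("ClassSpec",
    representation(
        classLabel = "character",
        centerFrequency = "numeric",
        bandwidth = "numeric",
        amplitudeScale = "numeric",
        spikeRate = "numeric",
        spikeAmplitude = "numeric",
        noiseSd = "numeric"
    )
)

setValidity("ClassSpec", function(object) {
    msg <- character()
    if (object@centerFrequency <= 0)
        msg <- c(msg, "centerFrequency must be positive")
    if (object@bandwidth <= 0)
        msg <- c(msg, "bandwidth must be positive")
    if (object@amplitudeScale < 0)
        msg <- c(msg, "amplitudeScale must be >= 0")
    if (object@spikeRate < 0)
        msg <- c(msg, "spikeRate must be >= 0")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a ClassSpec
#'
#' @param classLabel class identifier string.
#' @param centerFrequency resonance center frequency, Hz.
#' @param bandwidth resonance bandwidth, Hz.
#' @param amplitudeScale multiplicative gain on the oscillation
#'   (default 1).
#' @param spikeRate expected spikes/second (default 0).
#' @param spikeAmplitude spike peak amplitude (default 0).
#' @param noiseSd additive white-noise sd (default 0).
#' @return a [ClassSpec-class] object.
#' @examples
#' classSpec("alpha", centerFrequency = 10, bandwidth = 2, noiseSd = 0.2)
#' @export
classSpec <- function(classLabel, centerFrequency, bandwidth,
                      amplitudeScale = 1, spikeRate = 0,
                      spikeAmplitude = 0, noiseSd = 0) {
    new("ClassSpec",
        classLabel = as.character(classLabel),
        centerFrequency = as.numeric(centerFrequency),
        bandwidth = as.numeric(bandwidth),
        amplitudeScale = as.numeric(amplitudeScale),
        spikeRate = as.numeric(spikeRate),
        spikeAmplitude = as.numeric(spikeAmplitude),
        noiseSd = as.numeric(noiseSd))
}

#' DatasetSpec: a full synthetic dataset recipe
#'
#' @slot classes list of [ClassSpec-class] objects (>= 2 for
#'   classification fixtures).
#' @slot nSignalsPerClass number of independent signals per class.
#' @slot signalLength samples per signal.
#' @slot sampleRate Hz, shared by all classes.
#' @slot seed master seed; per-signal seeds are derived as
#'   `seed + (classIndex - 1) * nSignalsPerClass + (replicate - 1)`, so the
#'   master seed fully determines the dataset.
#'
#' @seealso [datasetSpec()], [generateDataset()], [bonnLikePreset()],
#'   [freiburgLikePreset()].
#' @exportClass DatasetSpec
setClass("DatasetSpec",
    representation(
        classes = "list",
        nSignalsPerClass = "integer",
        signalLength = "integer",
        sampleRate = "numeric",
        seed = "integer"
    )
)

setValidity("DatasetSpec", function(object) {
    msg <- character()
    if (!all(vapply(object@classes, is, logical(1), class2 = "ClassSpec")))
        msg <- c(msg, "'classes' must be a list of ClassSpec objects")
    if (length(object@classes) < 1L)
        msg <- c(msg, "at least one class is required")
    if (object@nSignalsPerClass < 1L)
        msg <- c(msg, "nSignalsPerClass must be >= 1")
    if (object@signalLength < 1L)
        msg <- c(msg, "signalLength must be >= 1")
    if (object@sampleRate <= 0)
        msg <- c(msg, "sampleRate must be positive")
    nyq <- object@sampleRate / 2
    for (cs in object@classes)
        if (is(cs, "ClassSpec") && cs@centerFrequency >= nyq)
            msg <- c(msg, sprintf(
                "class '%s': centerFrequency %.3g Hz is at or above Nyquist (%.3g Hz)",
                cs@classLabel, cs@centerFrequency, nyq))
    if (length(msg)) msg else TRUE
})

#' Construct a DatasetSpec
#'
#' @param classes list of [ClassSpec-class] objects.
#' @param nSignalsPerClass signals per class.
#' @param signalLength samples per signal.
#' @param sampleRate sampling rate in Hz.
#' @param seed master seed (integer).
#' @return a [DatasetSpec-class] object.
#' @export
datasetSpec <- function(classes, nSignalsPerClass, signalLength,
                        sampleRate, seed) {
    new("DatasetSpec",
        classes = classes,
        nSignalsPerClass = as.integer(nSignalsPerClass),
        signalLength = as.integer(signalLength),
        sampleRate = as.numeric(sampleRate),
        seed = as.integer(seed))
}
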