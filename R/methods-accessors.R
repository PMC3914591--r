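# Accessors and show methods.

#' @rdname Signal-class
setMethod("samples", "Signal", function(object) object@samples)
#' @rdname Signal-class
setMethod("sampleRate", "Signal", function(object) object@sampleRate)
#' @rdname Signal-class
setMethod("classLabel", "Signal", function(object) object@classLabel)
#' @rdname Signal-class
setMethod("sourceId", "Signal", function(object) object@sourceId)

#' @rdname Signal-class
#' @param x a `Signal`.
#' @export
setMethod("length", "Signal", function(x) length(x@samples))

setMethod("show", "Signal", function(object) {
    cat(sprintf("Signal '%s': %d samples @ %.4g Hz (%.2f s), label: %s\n",
                object@sourceId, length(object@samples), object@sampleRate,
                length(object@samples) / object@sampleRate,
                ifelse(is.na(object@classLabel), "<unlabeled>",
                       object@classLabel)))
})

#' @rdname WindowMatrix-class
setMethod("windowData", "WindowMatrix", function(object) object@windowData)
#' @rdname WindowMatrix-class
setMethod("windowLength", "WindowMatrix", function(object) object@windowLength)
#' @rdname WindowMatrix-class
setMethod("embeddingMode", "WindowMatrix", function(object) object@embeddingMode)
#' @rdname WindowMatrix-class
setMethod("rowLabels", "WindowMatrix", function(object) object@rowLabels)
#' @rdname WindowMatrix-class
setMethod("rowSources", "WindowMatrix", function(object) object@rowSources)
#' @rdname WindowMatrix-class
setMethod("rowWindows", "WindowMatrix", function(object) object@rowWindows)

#' @rdname WindowMatrix-class
#' @param x a `WindowMatrix`.
#' @export
setMethod("dim", "WindowMatrix", function(x) dim(x@windowData))

#' @rdname WindowMatrix-class
#' @export
setMethod("nrow", "WindowMatrix", function(x) nrow(x@windowData))

setMethod("show", "WindowMatrix", function(object) {
    labs <- unique(object@rowLabels)
    cat(sprintf("WindowMatrix: %d windows x %d samples (%s)\n",
                nrow(object@windowData), object@windowLength,
                object@embeddingMode))
    cat(sprintf("  sources: %d, labels: %s\n",
                length(unique(object@rowSources)),
                paste(ifelse(is.na(labs), "<unlabeled>", labs),
                      collapse = ", ")))
})

#' @rdname WindowPCA-class
setMethod("trainingMean", "WindowPCA", function(object) object@trainingMean)
#' @rdname WindowPCA-class
setMethod("pcLoadings", "WindowPCA", function(object) object@pcLoadings)
#' @rdname WindowPCA-class
setMethod("pcEigenvalues", "WindowPCA", function(object) object@pcEigenvalues)
#' @rdname WindowPCA-class
setMethod("windowLength", "WindowPCA", function(object) object@windowLength)
#' @rdname WindowPCA-class
setMethod("nTrainRows", "WindowPCA", function(object) object@nTrainRows)

setMethod("show", "WindowPCA", function(object) {
    ev <- object@pcEigenvalues
    tot <- sum(ev)
    top <- if (tot > 0) cumsum(ev)[seq_len(min(3, length(ev)))] / tot else
        rep(1, min(3, length(ev)))
    cat(sprintf("WindowPCA: l = %d, fitted on %d windows\n",
                object@windowLength, object@nTrainRows))
    cat(sprintf("  cumulative variance explained by first %d PCs: %s\n",
                length(top), paste(sprintf("%.3f", top), collapse = " ")))
})

#' @rdname FeatureSet-class
setMethod("featureValues", "FeatureSet", function(object) object@featureValues)
#' @rdname FeatureSet-class
setMethod("featureScheme", "FeatureSet", function(object) object@featureScheme)
#' @rdname FeatureSet-class
setMethod("rowLabels", "FeatureSet", function(object) object@rowLabels)
#' @rdname FeatureSet-class
setMethod("rowSources", "FeatureSet", function(object) object@rowSources)
#' @rdname FeatureSet-class
setMethod("rowWindows", "FeatureSet", function(object) object@rowWindows)

#' @rdname FeatureSet-class
#' @param x a `FeatureSet`.
#' @export
setMethod("dim", "FeatureSet", function(x) dim(x@featureValues))

setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet (%s): %d windows x %d features\n",
                object@featureScheme, nrow(object@featureValues),
                ncol(object@featureValues)))
    tab <- table(object@rowLabels, useNA = "ifany")
    cat("  windows per label:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname CVReport-class
setMethod("foldAccuracies", "CVReport", function(object) object@foldAccuracies)
#' @rdname CVReport-class
setMethod("meanAccuracy", "CVReport", function(object) object@meanAccuracy)
#' @rdname CVReport-class
setMethod("sdAccuracy", "CVReport", function(object) object@sdAccuracy)
#' @rdname CVReport-class
setMethod("foldSegmentAccuracies", "CVReport",
          function(object) object@foldSegmentAccuracies)
#' @rdname CVReport-class
setMethod("confusionTotals", "CVReport", function(object) object@confusionTotals)
#' @rdname CVReport-class
setMethod("configEcho", "CVReport", function(object) object@configEcho)

setMethod("show", "CVReport", function(object) {
    cfg <- object@configEcho
    cat(sprintf("CVReport: %s, l = %s, d = %s, %d-fold CV\n",
                cfg$scheme, cfg$window_length, cfg$d,
                length(object@foldAccuracies)))
    cat(sprintf("  window accuracy: %.3f +/- %.3f\n",
                object@meanAccuracy, object@sdAccuracy))
    if (length(object@foldSegmentAccuracies))
        cat(sprintf("  segment (majority-vote) accuracy: %.3f +/- %.3f\n",
                    mean(object@foldSegmentAccuracies),
                    stats::sd(object@foldSegmentAccuracies)))
})

setMethod("show", "ClassSpec", function(object) {
    cat(sprintf(
        "ClassSpec '%s': %.3g Hz peak (bw %.3g Hz), gain %.3g, spikes %.3g/s (amp %.3g), noise sd %.3g\n",
        object@classLabel, object@centerFrequency, object@bandwidth,
        object@amplitudeScale, object@spikeRate, object@spikeAmplitude,
        object@noiseSd))
})

setMethod("show", "DatasetSpec", function(object) {
    cat(sprintf(
        "DatasetSpec: %d classes x %d signals of %d samples @ %.4g Hz (seed %d)\n",
        length(object@classes), object@nSignalsPerClass,
        object@signalLength, object@sampleRate, object@seed))
    for (cs in object@classes) show(cs)
})
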