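# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @rdname Signal-class
#' @param object a package object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname Signal-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname Signal-class
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname Signal-class
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname WindowMatrix-class
#' @param object a package object.
#' @export
setGeneric("windowData", function(object) standardGeneric("windowData"))

#' @rdname WindowMatrix-class
#' @export
setGeneric("windowLength", function(object) standardGeneric("windowLength"))

#' @rdname WindowMatrix-class
#' @export
setGeneric("embeddingMode", function(object) standardGeneric("embeddingMode"))

#' @rdname WindowMatrix-class
#' @export
setGeneric("rowLabels", function(object) standardGeneric("rowLabels"))

#' @rdname WindowMatrix-class
#' @export
setGeneric("rowSources", function(object) standardGeneric("rowSources"))

#' @rdname WindowMatrix-class
#' @export
setGeneric("rowWindows", function(object) standardGeneric("rowWindows"))

#' @rdname WindowPCA-class
#' @param object a package object.
#' @export
setGeneric("trainingMean", function(object) standardGeneric("trainingMean"))

#' @rdname WindowPCA-class
#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))

#' @rdname WindowPCA-class
#' @export
setGeneric("pcEigenvalues", function(object) standardGeneric("pcEigenvalues"))

#' @rdname WindowPCA-class
#' @export
setGeneric("nTrainRows", function(object) standardGeneric("nTrainRows"))

#' @rdname FeatureSet-class
#' @param object a package object.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureScheme", function(object) standardGeneric("featureScheme"))

#' @rdname CVReport-class
#' @param object a package object.
#' @export
setGeneric("foldAccuracies", function(object) standardGeneric("foldAccuracies"))

#' @rdname CVReport-class
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))

#' @rdname CVReport-class
#' @export
setGeneric("sdAccuracy", function(object) standardGeneric("sdAccuracy"))

#' @rdname CVReport-class
#' @export
setGeneric("foldSegmentAccuracies",
           function(object) standardGeneric("foldSegmentAccuracies"))

#' @rdname CVReport-class
#' @export
setGeneric("confusionTotals", function(object) standardGeneric("confusionTotals"))

#' @rdname CVReport-class
#' @export
setGeneric("configEcho", function(object) standardGeneric("configEcho"))
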