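#' @rdname VOCPanel-class
#' @param object,x an object.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname VOCPanel-class
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname VOCExperiment-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VOCExperiment-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname BlankFilterResult-class
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname BlankFilterResult-class
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname LogRatioMatrix-class
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))

#' @rdname LogRatioMatrix-class
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' @rdname ImportanceFrequencyMatrix-class
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname ImportanceFrequencyMatrix-class
#' @export
setGeneric("shadowMax", function(x) standardGeneric("shadowMax"))

#' @rdname ImportanceFrequencyMatrix-class
#' @export
setGeneric("columnScores", function(x) standardGeneric("columnScores"))

#' @rdname ProximityMatrix-class
#' @export
setGeneric("proximity", function(x) standardGeneric("proximity"))

#' @rdname ProximityMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ModelResult-class
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname ModelResult-class
#' @export
setGeneric("modelAUC", function(x) standardGeneric("modelAUC"))

#' @rdname BinaryLabeling-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
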