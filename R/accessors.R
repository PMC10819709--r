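#' @rdname VOCPanel-class
#' @aliases compounds,VOCPanel-method
setMethod("compounds", "VOCPanel", function(x) x@compounds)

#' @rdname VOCPanel-class
setMethod("panelName", "VOCPanel", function(x) x@name)

#' @rdname VOCExperiment-class
setMethod("compounds", "VOCExperiment", function(x) rownames(x))

#' Intensity matrix in analysis orientation
#'
#' Returns the assay as a samples-by-compounds matrix (the orientation the
#' statistical machinery works in), with sample ids as row names.
#'
#' @rdname VOCExperiment-class
setMethod("intensities", "VOCExperiment", function(x) {
  m <- t(SummarizedExperiment::assay(x, "intensity"))
  rownames(m) <- colData(x)$sample_id
  m
})

#' @rdname VOCExperiment-class
setMethod("sampleData", "VOCExperiment", function(x) {
  df <- as.data.frame(colData(x))
  rownames(df) <- df$sample_id
  df
})

#' @rdname BlankFilterResult-class
setMethod("retainedFeatures", "BlankFilterResult", function(x) x@retained)

#' @rdname BlankFilterResult-class
setMethod("filterReport", "BlankFilterResult", function(x) x@perFeature)

#' @rdname LogRatioMatrix-class
setMethod("ratioValues", "LogRatioMatrix", function(x) x@values)

#' @rdname LogRatioMatrix-class
setMethod("pairIndex", "LogRatioMatrix", function(x) x@pairIndex)

#' @rdname ImportanceFrequencyMatrix-class
setMethod("freqMatrix", "ImportanceFrequencyMatrix", function(x) x@freq)

#' @rdname ImportanceFrequencyMatrix-class
setMethod("shadowMax", "ImportanceFrequencyMatrix", function(x) x@shadowMax)

#' @rdname ImportanceFrequencyMatrix-class
setMethod("columnScores", "ImportanceFrequencyMatrix",
          function(x) x@columnScores)

#' @rdname ProximityMatrix-class
setMethod("proximity", "ProximityMatrix", function(x) x@values)

#' @rdname ProximityMatrix-class
setMethod("sampleIds", "ProximityMatrix", function(x) x@sampleIds)

#' @rdname ModelResult-class
setMethod("probabilities", "ModelResult", function(x) x@probabilities)

#' @rdname ModelResult-class
setMethod("modelAUC", "ModelResult", function(x) x@auc)

#' @rdname ModelResult-class
setMethod("proximity", "ModelResult", function(x) x@proximity)

#' @rdname BinaryLabeling-class
setMethod("classLabels", "BinaryLabeling", function(x) {
  stats::setNames(x@labels, x@sampleIds)
})

setMethod("show", "VOCPanel", function(object) {
  cat("VOCPanel '", object@name, "' with ", length(object@compounds),
      " compounds\n", sep = "")
})

setMethod("show", "VOCExperiment", function(object) {
  cd <- colData(object)
  cat("VOCExperiment: ", nrow(object), " compounds x ", ncol(object),
      " samples\n", sep = "")
  cat("  roles:", paste(sprintf("%s=%d", names(table(cd$role)),
                                table(cd$role)), collapse = ", "), "\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "intensity")))
  cat("  missing entries:", nmiss, "\n")
})

setMethod("show", "BinaryLabeling", function(object) {
  cat("BinaryLabeling: ", sum(object@labels == "PSC"), " PSC-class / ",
      sum(object@labels == "IBD"), " IBD samples (",
      object@positivePatients, " / ", object@negativePatients,
      " unique patients)\n", sep = "")
})

setMethod("show", "BlankFilterResult", function(object) {
  cat("BlankFilterResult: ", length(object@retained), " of ",
      nrow(object@perFeature), " features retained\n", sep = "")
})

setMethod("show", "ImportanceFrequencyMatrix", function(object) {
  cat("ImportanceFrequencyMatrix: ", nrow(object@freq), " x ",
      ncol(object@freq), ", shadow max ", signif(object@shadowMax, 3),
      ", ", sum(object@freq[upper.tri(object@freq)] > 0),
      " surviving ratios\n", sep = "")
})

setMethod("show", "ProximityMatrix", function(object) {
  cat("ProximityMatrix: ", nrow(object@values), " samples\n", sep = "")
})

setMethod("show", "ModelResult", function(object) {
  cat("ModelResult: AUC ", round(object@auc, 3), " (sens ",
      round(object@sensitivity, 3), ", spec ",
      round(object@specificity, 3), ") on ",
      length(object@probabilities), " samples\n", sep = "")
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult: canonical r ", round(object@canonicalR, 3),
      ", mean p ", signif(object@meanP, 3), ", significant in ",
      round(100 * object@fracSignificant), "% of ", object@nIterations,
      " iterations\n", sep = "")
})
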