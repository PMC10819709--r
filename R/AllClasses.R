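#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

.GROUPS <- c("PSC", "PSC_IBD", "IBD")
.ROLES  <- c("biological", "mc_blank", "instrument_blank", "qc")
.BLOOD  <- c("ALP", "AST", "ALT", "bilirubin")

#' VOC panel: an ordered list of compound identities
#'
#' A panel names the compounds measured on one platform, in column order of
#' the corresponding feature table. Compound names are normalised to lower
#' case (punctuation preserved) so that differently capitalised spellings of
#' the same analyte join safely across tables.
#'
#' @slot name short platform identifier, e.g. `"fecal"` or `"breath"`.
#' @slot compounds character vector of unique, non-empty compound names.
#' @export
setClass("VOCPanel", slots = c(name = "character", compounds = "character"))

setValidity("VOCPanel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@compounds) == 0L || any(!nzchar(object@compounds)))
    msg <- c(msg, "'compounds' must be non-empty strings")
  if (anyDuplicated(object@compounds))
    msg <- c(msg, "compound names must be unique within a panel")
  if (length(msg)) msg else TRUE
})

#' Sample-by-compound VOC intensity container
#'
#' `VOCExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' one assay, `"intensity"`, holding non-negative GC-MS peak intensities
#' (compounds in rows, samples in columns; `NA` marks a value below detection
#' or otherwise not measured — never coded as zero, since zero is a meaningful
#' intensity for the blank-retention rule). Per-sample metadata lives in
#' `colData`: `sample_id`, `patient_id`, `group` (PSC / PSC_IBD / IBD, `NA`
#' for non-biological samples), `role` (biological, mc_blank,
#' instrument_blank, qc), `duplicate_index` (>= 1), `water_content` (percent),
#' optional blood markers (`ALP`, `AST`, `ALT`, `bilirubin`) and
#' `severity_score` (a precomputed Amsterdam-Oxford-like covariate).
#'
#' @export
setClass("VOCExperiment", contains = "SummarizedExperiment")

setValidity("VOCExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  v <- SummarizedExperiment::assay(object, "intensity")
  if (any(v < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "patient_id", "group", "role", "duplicate_index")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing sample metadata column(s):",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (!all(cd$role %in% .ROLES))
    msg <- c(msg, paste("role must be one of:", paste(.ROLES, collapse = ", ")))
  bio <- cd$role == "biological"
  if (any(bio & (is.na(cd$group) | !cd$group %in% .GROUPS)))
    msg <- c(msg, "biological samples must carry a group (PSC, PSC_IBD, IBD)")
  if (any(!bio & !is.na(cd$group)))
    msg <- c(msg, "blank/QC samples must not carry a group")
  if (any(is.na(cd$duplicate_index)) || any(cd$duplicate_index < 1))
    msg <- c(msg, "duplicate_index must be >= 1")
  if ("water_content" %in% colnames(cd)) {
    w <- cd$water_content
    if (any(!is.na(w) & (w < 0 | w > 100)))
      msg <- c(msg, "water_content must lie in [0, 100]")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "compound (row) names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Binary PSC-vs-IBD labelling of biological samples
#'
#' PSC and PSC/IBD patients are merged into one positive class ("PSC");
#' IBD-only patients form the negative class ("IBD").
#'
#' @slot labels factor with levels `c("IBD", "PSC")`, one per sample.
#' @slot sampleIds,patientIds character vectors aligned with `labels`.
#' @slot positivePatients,negativePatients unique-patient counts per class.
#' @export
setClass("BinaryLabeling",
  slots = c(labels = "factor", sampleIds = "character",
            patientIds = "character", positivePatients = "integer",
            negativePatients = "integer"))

setValidity("BinaryLabeling", function(object) {
  msg <- character()
  if (!identical(levels(object@labels), c("IBD", "PSC")))
    msg <- c(msg, "labels must be a factor with levels c('IBD', 'PSC')")
  n <- length(object@labels)
  if (length(object@sampleIds) != n || length(object@patientIds) != n)
    msg <- c(msg, "sampleIds/patientIds must align with labels")
  if (anyNA(object@labels))
    msg <- c(msg, "every biological sample must map to exactly one class")
  if (length(msg)) msg else TRUE
})

#' Result of the blank-based feature retention rule
#'
#' @slot retained names of features kept by the rule.
#' @slot perFeature data.frame with one row per feature: `sample_median`,
#'   `blank_median`, `blank_iqr`, `threshold`, `kept`, `reason`.
#' @slot quantileType the quantile convention used for the IQR (R type 7,
#'   linear interpolation), recorded so tests can pin it.
#' @export
setClass("BlankFilterResult",
  slots = c(retained = "character", perFeature = "data.frame",
            quantileType = "integer"))

setValidity("BlankFilterResult", function(object) {
  pf <- object@perFeature
  need <- c("feature", "sample_median", "blank_median", "blank_iqr",
            "threshold", "kept", "reason")
  if (!all(need %in% colnames(pf)))
    return("perFeature must contain the documented columns")
  ok <- !is.na(pf$sample_median) & !is.na(pf$threshold)
  if (any(pf$kept[ok] != (pf$sample_median[ok] > pf$threshold[ok])))
    return("kept flag must equal sample_median > blank_median + 3 * IQR (strict)")
  if (!setequal(object@retained, pf$feature[pf$kept]))
    return("'retained' must list exactly the kept features")
  TRUE
})

#' Pairwise log-ratio matrix
#'
#' Holds the natural-log ratios of all unordered feature pairs in canonical
#' orientation (numerator index < denominator index), together with an index
#' mapping each ratio column back to its original compound pair. By
#' construction every entry is invariant to per-sample multiplicative
#' (dilution) scaling of the raw intensities.
#'
#' @slot values n_samples x n_ratios numeric matrix.
#' @slot pairIndex data.frame with columns `ratio`, `num`, `den`,
#'   `num_index`, `den_index`.
#' @export
setClass("LogRatioMatrix",
  slots = c(values = "matrix", pairIndex = "data.frame"))

setValidity("LogRatioMatrix", function(object) {
  if (ncol(object@values) != nrow(object@pairIndex))
    return("pairIndex must have one row per ratio column")
  if (any(object@pairIndex$num_index >= object@pairIndex$den_index))
    return("canonical orientation requires num_index < den_index")
  TRUE
})

#' Square importance-frequency matrix from stability selection
#'
#' Entry (i, j) is the frequency, across selection iterations, with which the
#' log ratio of compounds i and j reached the per-iteration importance
#' criterion. Frequencies not exceeding the maximum frequency attained by any
#' shadow feature are zeroed before ranking; per-compound scores are the
#' column sums of the thresholded matrix.
#'
#' @slot freq p x p numeric matrix in `[0, 1]`, zero diagonal, filled
#'   symmetrically.
#' @slot shadowMax maximum selection frequency attained by a shadow feature.
#' @slot columnScores per-compound totals (column sums of `freq`).
#' @slot nIterations number of stability-selection iterations run.
#' @export
setClass("ImportanceFrequencyMatrix",
  slots = c(freq = "matrix", shadowMax = "numeric",
            columnScores = "numeric", nIterations = "integer"))

setValidity("ImportanceFrequencyMatrix", function(object) {
  f <- object@freq
  msg <- character()
  if (nrow(f) != ncol(f)) msg <- c(msg, "freq must be square")
  if (any(f < 0 | f > 1)) msg <- c(msg, "frequencies must lie in [0, 1]")
  if (any(diag(f) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(f != 0 & f <= object@shadowMax))
    msg <- c(msg, "nonzero entries must exceed shadowMax")
  if (!isTRUE(all.equal(unname(object@columnScores), unname(colSums(f)))))
    msg <- c(msg, "columnScores must be the column sums of freq")
  if (length(msg)) msg else TRUE
})

#' Tree-ensemble proximity matrix
#'
#' Pairwise sample similarity in `[0, 1]` measured as the fraction of trees in
#' which two samples share a terminal leaf (for fitted models, counted only
#' over trees where both samples are out of bag).
#'
#' @slot values symmetric n x n matrix with unit diagonal.
#' @slot sampleIds sample (or patient) identifiers for rows/columns.
#' @export
setClass("ProximityMatrix",
  slots = c(values = "matrix", sampleIds = "character"))

setValidity("ProximityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v) || nrow(v) != length(object@sampleIds))
    msg <- c(msg, "values must be square and match sampleIds")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
  if (any(abs(diag(v) - 1) > 1e-8)) msg <- c(msg, "diagonal must equal 1")
  if (any(v < -1e-8 | v > 1 + 1e-8)) msg <- c(msg, "entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fitted classification model summary
#'
#' @slot probabilities per-sample mean predicted probability of the PSC class
#'   over internal-validation iterations (named by sample id).
#' @slot labels factor of true classes, levels `c("IBD", "PSC")`.
#' @slot sampleInfo data.frame with `sample_id`, `patient_id`, `label`.
#' @slot selected list describing the feature set the model used (ratio pairs
#'   or raw feature names).
#' @slot proximity [ProximityMatrix-class] from the final all-data model.
#' @slot auc,sensitivity,specificity,threshold ROC summary at the
#'   Youden-optimal operating point.
#' @slot rocCurve data.frame of the full ROC curve.
#' @slot pcoa n x 2 principal-coordinate embedding of 1 - proximity.
#' @slot extra list of auxiliary per-analysis output.
#' @export
setClass("ModelResult",
  slots = c(probabilities = "numeric", labels = "factor",
            sampleInfo = "data.frame", selected = "list",
            proximity = "ProximityMatrix", auc = "numeric",
            sensitivity = "numeric", specificity = "numeric",
            threshold = "numeric", rocCurve = "data.frame",
            pcoa = "matrix", extra = "list"))

setValidity("ModelResult", function(object) {
  msg <- character()
  p <- object@probabilities
  if (any(!is.na(p) & (p < 0 | p > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cross-platform correlation summary
#'
#' @slot selectedX,selectedY screened feature names per platform.
#' @slot canonicalR Fisher-z-averaged first canonical correlation.
#' @slot meanP mean permutation p-value of the first canonical variate.
#' @slot fracSignificant fraction of iterations with p below alpha.
#' @slot univariate data.frame of averaged Pearson correlations with raw and
#'   Benjamini-Hochberg adjusted p-values.
#' @slot significant whether the averaged canonical association met alpha.
#' @slot nIterations number of imputation iterations averaged over.
#' @export
setClass("CorrelationResult",
  slots = c(selectedX = "character", selectedY = "character",
            canonicalR = "numeric", meanP = "numeric",
            fracSignificant = "numeric", univariate = "data.frame",
            significant = "logical", nIterations = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (length(object@canonicalR) &&
      (object@canonicalR < -1e-9 || object@canonicalR > 1 + 1e-9))
    msg <- c(msg, "canonicalR must lie in [0, 1]")
  if (length(object@fracSignificant) &&
      (object@fracSignificant < 0 || object@fracSignificant > 1))
    msg <- c(msg, "fracSignificant must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
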