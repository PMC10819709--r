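#' Duplicate-safe, class-stratified train/test split
#'
#' Sampling happens at the patient level, so both duplicates of a patient
#' always fall on the same side of the split; class-wise fractions follow
#' the configuration (83% of PSC-class, 73% of IBD patients by default).
#'
#' @param sample_info data.frame with `sample_id`, `patient_id`, `label`
#'   (or a [BinaryLabeling-class]).
#' @param config a [selectionConfig()] (its `psc_subsample` and
#'   `ibd_subsample` are used).
#' @param seed integer seed.
#' @return list with `train` and `test` sample-id vectors.
#' @export
splitDuplicateSafe <- function(sample_info, config = selectionConfig(),
                               seed = 1L) {
  if (is(sample_info, "BinaryLabeling"))
    sample_info <- data.frame(sample_id = sample_info@sampleIds,
                              patient_id = sample_info@patientIds,
                              label = as.character(sample_info@labels),
                              stringsAsFactors = FALSE)
  lab_patient <- tapply(sample_info$label, sample_info$patient_id,
                        function(v) v[1L])
  samples_of <- split(sample_info$sample_id, sample_info$patient_id)
  pool <- withr::with_seed(as.integer(seed),
    .subsample_patients(samples_of, lab_patient, config))
  train <- unlist(samples_of[pool], use.names = FALSE)
  list(train = train,
       test = setdiff(sample_info$sample_id, train))
}

# Iterated duplicate-safe evaluation engine. z_builder(seed) returns the
# full samples-by-features matrix for one iteration (re-imputed when the
# table has missing entries). Both duplicates of a training patient enter
# the training set, letting the trees grow on the full material.
.iterated_rf_eval <- function(z_builder, labeling, config, n_iterations) {
  lab_sample <- classLabels(labeling)
  lab_patient <- tapply(as.character(labeling@labels),
                        labeling@patientIds, function(v) v[1L])
  samples_of <- split(labeling@sampleIds, labeling@patientIds)
  n <- length(lab_sample)
  prob_sum <- stats::setNames(numeric(n), names(lab_sample))
  prob_n <- stats::setNames(numeric(n), names(lab_sample))
  aucs <- numeric(n_iterations)
  seeds <- .substreams(config$seed + 2L, 2L * n_iterations)
  for (i in seq_len(n_iterations)) {
    s <- seeds[(2L * (i - 1L) + 1L):(2L * i)]
    z <- z_builder(s[2L])
    pool <- withr::with_seed(s[1L],
      .subsample_patients(samples_of, lab_patient, config))
    train <- unlist(samples_of[pool], use.names = FALSE)
    test <- setdiff(names(lab_sample), train)
    y_tr <- droplevels(lab_sample[train])
    if (nlevels(y_tr) < 2L)
      stop("training pool contains a single class")
    fit <- withr::with_seed(s[1L], randomForest::randomForest(
      z[train, , drop = FALSE], y_tr, ntree = config$rf_trees))
    if (length(test)) {
      pr <- stats::predict(fit, z[test, , drop = FALSE],
                           type = "prob")[, "PSC"]
      prob_sum[test] <- prob_sum[test] + pr
      prob_n[test] <- prob_n[test] + 1
      aucs[i] <- .auc_fast(pr, lab_sample[test])
    } else aucs[i] <- NA_real_
  }
  covered <- prob_n > 0
  if (!all(covered))
    warning(sum(!covered), " sample(s) never held out; ",
            "increase n_iterations for full coverage")
  list(probabilities = ifelse(covered, prob_sum / prob_n, NA_real_),
       per_iteration_auc = aucs)
}

.final_model_proximity <- function(z, lab_sample, config) {
  fit <- withr::with_seed(config$seed + 3L, randomForest::randomForest(
    z, lab_sample, ntree = config$rf_trees,
    proximity = TRUE, oob.prox = TRUE))
  .new_proximity(fit$proximity, rownames(z))
}

#' Fit and evaluate the final classification model
#'
#' Over `n_iterations` duplicate-safe splits the model is refit on the
#' training pool (both duplicates included) and held-out samples are
#' predicted; per-sample probabilities are averaged across the iterations in
#' which the sample was held out. A final all-data forest provides the
#' out-of-bag proximity matrix (co-terminal-leaf frequency counted over
#' trees where both samples are out of bag), embedded by principal
#' coordinates for visualisation. ROC metrics are computed from the averaged
#' probabilities with the Youden-optimal operating point.
#'
#' @param x a [VOCExperiment-class]; only biological samples are used.
#' @param labeling a [BinaryLabeling-class]; defaults to merging the PSC
#'   groups of `x`.
#' @param selected either a data.frame of ratio pairs (`num`, `den`) from
#'   [rankAndOptimize()], or a character vector of raw feature names (used
#'   on the natural-log scale), or a single-column numeric matrix of an
#'   external covariate.
#' @param config a [selectionConfig()].
#' @param n_iterations evaluation iterations (defaults to
#'   `config$n_iterations`).
#' @return a [ModelResult-class].
#' @export
fitEvaluate <- function(x, labeling = NULL, selected,
                        config = selectionConfig(),
                        n_iterations = config$n_iterations) {
  x <- subsetByRole(x, "biological")
  if (is.null(labeling)) labeling <- mergePscGroups(x)
  m <- intensities(x)
  stopifnot(identical(rownames(m), labeling@sampleIds))
  lab_sample <- classLabels(labeling)

  if (is.data.frame(selected)) {
    z_builder <- function(seed) ratioColumns(imputeMissing(m, seed), selected)
    sel_desc <- list(type = "log-ratio", ratios = selected)
  } else if (is.character(selected)) {
    miss <- setdiff(selected, colnames(m))
    if (length(miss))
      stop("unknown feature(s): ", paste(miss, collapse = ", "))
    z_builder <- function(seed)
      log(imputeMissing(m[, selected, drop = FALSE], seed))
    sel_desc <- list(type = "raw", features = selected)
  } else {
    zfix <- as.matrix(selected)
    if (is.null(colnames(zfix))) colnames(zfix) <- "covariate"
    rownames(zfix) <- rownames(m)
    z_builder <- function(seed) zfix
    sel_desc <- list(type = "covariate", features = colnames(zfix))
  }

  ev <- .iterated_rf_eval(z_builder, labeling, config, n_iterations)
  prox <- .final_model_proximity(z_builder(config$seed + 4L), lab_sample,
                                 config)
  emb <- proximityPCoA(prox, k = 2L)
  keep <- !is.na(ev$probabilities)
  roc <- rocMetrics(ev$probabilities[keep], lab_sample[keep])
  new("ModelResult",
      probabilities = ev$probabilities, labels = lab_sample,
      sampleInfo = data.frame(sample_id = labeling@sampleIds,
                              patient_id = labeling@patientIds,
                              label = as.character(labeling@labels),
                              stringsAsFactors = FALSE),
      selected = sel_desc, proximity = prox,
      auc = roc$auc, sensitivity = roc$sensitivity,
      specificity = roc$specificity, threshold = roc$threshold,
      rocCurve = roc$curve, pcoa = emb$coordinates,
      extra = list(per_iteration_auc = ev$per_iteration_auc,
                   pcoa_eigenvalues = emb$eigenvalues))
}

#' ROC summary with Youden-optimal operating point
#'
#' Trapezoidal AUC over all thresholds (ties counted half), with the
#' operating point chosen to maximise the Youden index
#' (sensitivity + specificity - 1); when several thresholds tie, the first
#' reported by the ROC machinery is taken.
#'
#' @param probabilities numeric scores for the PSC class.
#' @param labels factor with levels `c("IBD", "PSC")` (or coercible).
#' @return list with `auc`, `sensitivity`, `specificity`, `threshold` and
#'   `curve` (data.frame of the full ROC curve).
#' @export
rocMetrics <- function(probabilities, labels) {
  labels <- .as_labels(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present to compute ROC metrics")
  r <- pROC::roc(response = labels, predictor = probabilities,
                 levels = c("IBD", "PSC"), direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1L, , drop = FALSE]
  list(auc = as.numeric(pROC::auc(r)),
       sensitivity = best$sensitivity,
       specificity = best$specificity,
       threshold = best$threshold,
       curve = data.frame(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities))
}

#' Classifier on fecal water content alone
#'
#' Bias check: a model fitted on the dry-weight covariate only. Also returns
#' the per-sample averaged probability against the absolute deviation from
#' mean water content, the diagnostic used to show that extreme humidity
#' lowers prediction certainty without driving the classification.
#'
#' @param x,labeling,config,n_iterations as in [fitEvaluate()].
#' @return a [ModelResult-class]; `extra$water_scatter` holds the
#'   probability-vs-deviation table.
#' @export
waterContentModel <- function(x, labeling = NULL,
                              config = selectionConfig(),
                              n_iterations = config$n_iterations) {
  x <- subsetByRole(x, "biological")
  sd_ <- sampleData(x)
  if (anyNA(sd_$water_content))
    stop("missing water content for sample(s): ",
         paste(sd_$sample_id[is.na(sd_$water_content)], collapse = ", "))
  if (stats::sd(sd_$water_content) == 0)
    stop("no variation in water content")
  w <- matrix(sd_$water_content, ncol = 1L,
              dimnames = list(sd_$sample_id, "water_content"))
  res <- fitEvaluate(x, labeling, selected = w, config = config,
                     n_iterations = n_iterations)
  dev <- abs(sd_$water_content - mean(sd_$water_content))
  res@extra$water_scatter <- data.frame(
    sample_id = sd_$sample_id, water_deviation = dev,
    probability = res@probabilities[sd_$sample_id],
    label = as.character(res@labels), row.names = NULL)
  res
}

#' Permutation pseudo-F test of a covariate on proximity structure
#'
#' Tests whether a per-sample covariate explains the sample dissimilarity
#' structure `1 - proximity`, using the distance-based pseudo-F statistic
#' with a permutation null: `p = (1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param prox a [ProximityMatrix-class].
#' @param covariate numeric vector, one value per sample.
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F) and `p_value`.
#' @export
proximityCovariateTest <- function(prox, covariate, n_perm = 999L,
                                   seed = 1L) {
  stopifnot(is(prox, "ProximityMatrix"))
  if (n_perm < 99L) stop("n_perm must be at least 99")
  v <- proximity(prox)
  if (length(covariate) != nrow(v))
    stop("covariate length must match the proximity matrix")
  d <- stats::as.dist(1 - v)
  df <- data.frame(covariate = as.numeric(covariate))
  fit <- withr::with_seed(as.integer(seed),
    vegan::adonis2(d ~ covariate, data = df, permutations = n_perm))
  list(statistic = fit$F[1L], p_value = fit$`Pr(>F)`[1L])
}

#' AUC within severity strata of the positive class
#'
#' Recomputes the AUC using only positive-class samples whose severity score
#' falls in the requested quantile band (all negatives retained). Bands are
#' defined on the empirical ranks of the positive samples' scores, so bands
#' such as (0, 0.5] and (0.5, 1] partition the positives disjointly and
#' exhaustively.
#'
#' @param result a [ModelResult-class].
#' @param severity numeric severity scores named by sample id (positives;
#'   defaults to the `severity_score` carried in `result@sampleInfo` when
#'   absent there, pass explicitly).
#' @param fractions list of `(lo, hi]` quantile bands.
#' @return named numeric vector of per-stratum AUCs.
#' @export
stratifiedAuc <- function(result, severity,
                          fractions = list(c(0, 0.5), c(0.5, 1))) {
  stopifnot(is(result, "ModelResult"))
  probs <- result@probabilities
  labs <- result@labels
  pos_ids <- names(labs)[labs == "PSC"]
  severity <- severity[pos_ids]
  if (anyNA(severity))
    stop("severity scores required for all positive-class samples")
  rk <- rank(severity, ties.method = "first") / length(severity)
  out <- vapply(fractions, function(fr) {
    in_band <- rk > fr[1L] & rk <= fr[2L]
    if (!any(in_band)) stop("empty severity stratum (",
                            fr[1L], ", ", fr[2L], "]")
    ids <- c(pos_ids[in_band], names(labs)[labs == "IBD"])
    keep <- ids[!is.na(probs[ids])]
    .auc_fast(probs[keep], labs[keep])
  }, numeric(1L))
  names(out) <- vapply(fractions, function(fr)
    sprintf("(%g,%g]", fr[1L], fr[2L]), character(1L))
  out
}
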