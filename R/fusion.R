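#' Configuration for proximity stacking
#'
#' @param weight_grid candidate fecal weights `w` in `[0, 1]` (the breath
#'   weight is `1 - w`); default 0 to 1 in steps of 0.05.
#' @param n_iterations internal-validation iterations for the fused model.
#' @param train_fraction patient-level training fraction per class.
#' @param rf_trees trees per forest.
#' @param var_mass fraction of positive eigenvalue mass retained when
#'   embedding the fused proximities.
#' @param seed integer root seed.
#' @export
fusionConfig <- function(weight_grid = seq(0, 1, by = 0.05),
                         n_iterations = 50L, train_fraction = 0.76,
                         rf_trees = 300L, var_mass = 0.9, seed = 1L) {
  w <- sort(unique(as.numeric(weight_grid)))
  if (length(w) == 0L || any(w < 0 | w > 1))
    stop("weight_grid values must lie in [0, 1]")
  structure(list(weight_grid = w,
                 n_iterations = .check_count(n_iterations, "n_iterations", 1L),
                 train_fraction = .check_fraction(train_fraction,
                                                 "train_fraction"),
                 rf_trees = .check_count(rf_trees, "rf_trees", 1L),
                 var_mass = .check_fraction(var_mass, "var_mass"),
                 seed = .check_count(seed, "seed", 0L)),
            class = "FusionConfig")
}

#' Align two platform models to a common patient index
#'
#' Intersects the patients present on both platforms and collapses fecal
#' duplicates to the patient level by averaging their proximity rows and
#' columns (the breath platform has one sample per patient, so fusion must
#' happen at patient grain).
#'
#' @param fecal,breath [ModelResult-class] objects carrying sample-level
#'   patient ids.
#' @return list with `patients`, `P_fecal`, `P_breath` (patient-level
#'   [ProximityMatrix-class]), and `labels` (factor per patient).
#' @export
alignSamples <- function(fecal, breath) {
  stopifnot(is(fecal, "ModelResult"), is(breath, "ModelResult"))
  collapse <- function(res) {
    si <- res@sampleInfo
    P <- proximity(proximity(res))
    pats <- unique(si$patient_id)
    A <- vapply(pats, function(p)
      as.numeric(si$patient_id == p) / sum(si$patient_id == p),
      numeric(nrow(si)))
    M <- t(A) %*% P %*% A
    dimnames(M) <- list(pats, pats)
    list(P = M,
         labels = stats::setNames(
           si$label[!duplicated(si$patient_id)], pats))
  }
  cf <- collapse(fecal)
  cb <- collapse(breath)
  common <- intersect(rownames(cf$P), rownames(cb$P))
  if (length(common) == 0L)
    stop("no patients shared between the two platforms")
  lab <- factor(cf$labels[common], levels = c("IBD", "PSC"))
  list(patients = common,
       P_fecal = .new_proximity(cf$P[common, common, drop = FALSE], common),
       P_breath = .new_proximity(cb$P[common, common, drop = FALSE], common),
       labels = stats::setNames(lab, common))
}

#' Weighted average of two platform proximity matrices
#'
#' `P = w * P_fecal + (1 - w) * P_breath`, entrywise; all proximity
#' invariants (symmetry, unit diagonal, `[0, 1]` range) are preserved for
#' any `w` in `[0, 1]`.
#'
#' @param P_fecal,P_breath [ProximityMatrix-class] objects aligned to the
#'   same patient index.
#' @param w fecal weight in `[0, 1]`.
#' @return a [ProximityMatrix-class].
#' @export
stackProximities <- function(P_fecal, P_breath, w) {
  stopifnot(is(P_fecal, "ProximityMatrix"), is(P_breath, "ProximityMatrix"))
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("weight w must lie in [0, 1]")
  if (!identical(sampleIds(P_fecal), sampleIds(P_breath)))
    stop("matrices must be aligned to the same patient index")
  vals <- w * proximity(P_fecal) + (1 - w) * proximity(P_breath)
  new("ProximityMatrix", values = vals, sampleIds = sampleIds(P_fecal))
}

#' Final classifier on fused proximities
#'
#' The fused proximity matrix is embedded by principal coordinates
#' (retaining the leading axes explaining at least `var_mass` of the
#' positive eigenvalue mass) and a Random Forest is trained on the
#' coordinates, evaluated by class-stratified internal validation at the
#' patient level.
#'
#' @param P a fused [ProximityMatrix-class] at patient grain.
#' @param labels factor per patient, levels `c("IBD", "PSC")`.
#' @param config a [fusionConfig()].
#' @return a [ModelResult-class].
#' @export
fitFused <- function(P, labels, config = fusionConfig()) {
  stopifnot(is(P, "ProximityMatrix"))
  labels <- .as_labels(labels)
  ids <- sampleIds(P)
  names(labels) <- ids
  n <- length(ids)
  emb <- proximityPCoA(P, k = n - 1L)
  pos <- pmax(emb$eigenvalues, 0)
  if (sum(pos) <= 0) stop("fused proximity matrix has rank 0")
  k <- which(cumsum(pos) / sum(pos) >= config$var_mass)[1L]
  k <- max(2L, min(k, ncol(emb$coordinates)))
  z <- emb$coordinates[, seq_len(k), drop = FALSE]
  colnames(z) <- paste0("PCo", seq_len(k))
  rownames(z) <- ids

  labeling <- new("BinaryLabeling", labels = labels, sampleIds = ids,
                  patientIds = ids,
                  positivePatients = sum(labels == "PSC"),
                  negativePatients = sum(labels == "IBD"))
  cfg <- selectionConfig(n_iterations = config$n_iterations,
                         psc_subsample = config$train_fraction,
                         ibd_subsample = config$train_fraction,
                         rf_trees = config$rf_trees, seed = config$seed)
  ev <- .iterated_rf_eval(function(seed) z, labeling, cfg,
                          config$n_iterations)
  keep <- !is.na(ev$probabilities)
  roc <- rocMetrics(ev$probabilities[keep], labels[keep])
  new("ModelResult",
      probabilities = ev$probabilities, labels = labels,
      sampleInfo = data.frame(sample_id = ids, patient_id = ids,
                              label = as.character(labels),
                              stringsAsFactors = FALSE),
      selected = list(type = "fused-pcoa", n_coordinates = k),
      proximity = P, auc = roc$auc, sensitivity = roc$sensitivity,
      specificity = roc$specificity, threshold = roc$threshold,
      rocCurve = roc$curve, pcoa = z[, 1:2, drop = FALSE],
      extra = list(per_iteration_auc = ev$per_iteration_auc,
                   pcoa_eigenvalues = emb$eigenvalues))
}

#' Grid search for the platform fusion weight
#'
#' Evaluates the fused model at every weight of the grid by internal
#' validation and returns the weight maximising the mean AUC; exact ties are
#' broken toward the weight closest to 0.5 (an agnostic mix).
#'
#' @param P_fecal,P_breath aligned patient-level proximity matrices.
#' @param labels factor per patient.
#' @param config a [fusionConfig()].
#' @return list with `w` (optimum), `auc_table` (per-weight AUCs) and
#'   `result` (the [ModelResult-class] at the optimum).
#' @export
optimizeWeight <- function(P_fecal, P_breath, labels,
                           config = fusionConfig()) {
  grid <- config$weight_grid
  fits <- lapply(grid, function(w)
    fitFused(stackProximities(P_fecal, P_breath, w), labels, config))
  aucs <- vapply(fits, modelAUC, numeric(1L))
  best_auc <- max(aucs)
  cand <- which(aucs == best_auc)
  w_star <- grid[cand[which.min(abs(grid[cand] - 0.5))]]
  list(w = w_star,
       auc_table = data.frame(w = grid, auc = aucs),
       result = fits[[which(grid == w_star)]])
}
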