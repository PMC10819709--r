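#' Configuration for shadow-feature stability selection
#'
#' Defaults follow the study's procedure: 500 iterations, a 76/24
#' train/validation ratio realised through class-wise patient subsampling of
#' 83% of PSC-class and 73% of IBD cases per iteration, and an importance
#' criterion of at least 40% of the per-iteration maximum importance.
#'
#' @param n_iterations stability-selection iterations.
#' @param train_fraction nominal training share (used where a single overall
#'   fraction is needed, e.g. patient-level fused models).
#' @param importance_threshold_fraction per-iteration importance criterion,
#'   as a fraction of the maximum importance.
#' @param psc_subsample,ibd_subsample class-wise patient subsampling rates
#'   defining each iteration's modelling pool; the remainder is that
#'   iteration's held-out set.
#' @param rf_trees trees per forest.
#' @param seed integer root seed.
#' @export
selectionConfig <- function(n_iterations = 500L, train_fraction = 0.76,
                            importance_threshold_fraction = 0.40,
                            psc_subsample = 0.83, ibd_subsample = 0.73,
                            rf_trees = 500L, seed = 1L) {
  structure(list(
    n_iterations = .check_count(n_iterations, "n_iterations", 1L),
    train_fraction = .check_fraction(train_fraction, "train_fraction"),
    importance_threshold_fraction =
      .check_fraction(importance_threshold_fraction,
                      "importance_threshold_fraction"),
    psc_subsample = .check_fraction(psc_subsample, "psc_subsample"),
    ibd_subsample = .check_fraction(ibd_subsample, "ibd_subsample"),
    rf_trees = .check_count(rf_trees, "rf_trees", 1L),
    seed = .check_count(seed, "seed", 0L)),
    class = "SelectionConfig")
}

# Class-wise patient subsample; returns patient ids for the modelling pool.
.subsample_patients <- function(pats, labels_per_patient, cfg) {
  pool <- character(0)
  for (cls in c("PSC", "IBD")) {
    ids <- names(labels_per_patient)[labels_per_patient == cls]
    frac <- if (cls == "PSC") cfg$psc_subsample else cfg$ibd_subsample
    n_take <- min(length(ids), max(2L, round(frac * length(ids))))
    pool <- c(pool, sample(ids, n_take))
  }
  pool
}

# Rank-based AUC of the PSC class (equivalent to the trapezoidal rule with
# ties counted half); used inside optimisation loops.
.auc_fast <- function(probs, labels) {
  pos <- labels == "PSC"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Importance-frequency stability selection over pairwise log ratios
#'
#' For each iteration the cohort is subsampled class-wise at the patient
#' level (one randomly chosen duplicate per patient, so duplicate pairs never
#' inflate the importance model), missing values are re-imputed, the log
#' ratios are expanded, an equal number of shadow ratios is appended, and a
#' Random Forest records which ratio columns reach the per-iteration
#' importance criterion (permutation importance at or above
#' `importance_threshold_fraction` of the iteration maximum). Ratio
#' frequencies not exceeding the maximum shadow frequency are zeroed; the
#' surviving frequencies fill a square compound-by-compound matrix
#' symmetrically, and compounds are scored by column sums.
#'
#' Each shadow ratio is the real ratio column under a sample-level
#' permutation drawn once and held fixed across all iterations. A fixed
#' permutation carries its own cohort-level spurious label association from
#' iteration to iteration, exactly as a truly uninformative real ratio does,
#' so the maximum shadow frequency is a null threshold for selection
#' *stability* — re-permuting every iteration would wash shadow associations
#' out and let persistent chance associations survive.
#'
#' @param x a [VOCExperiment-class]; only biological samples are used.
#' @param labeling a [BinaryLabeling-class] (or labels coercible to one)
#'   aligned with the biological samples.
#' @param config a [selectionConfig()].
#' @return an [ImportanceFrequencyMatrix-class].
#' @export
importanceFrequency <- function(x, labeling, config = selectionConfig()) {
  stopifnot(inherits(config, "SelectionConfig"))
  x <- subsetByRole(x, "biological")
  if (!is(labeling, "BinaryLabeling")) labeling <- mergePscGroups(x)
  m <- intensities(x)
  stopifnot(identical(rownames(m), labeling@sampleIds))
  lab_sample <- classLabels(labeling)
  lab_patient <- tapply(as.character(labeling@labels),
                        labeling@patientIds, function(v) v[1L])
  if (min(table(factor(lab_patient, c("IBD", "PSC")))) < 2L)
    stop("each class needs at least 2 patients")
  samples_of <- split(labeling@sampleIds, labeling@patientIds)

  p <- ncol(m)
  n_ratio <- p * (p - 1L) / 2L
  pats <- names(samples_of)
  n_pat <- length(pats)
  hit_real <- numeric(n_ratio)
  hit_shadow <- numeric(n_ratio)
  seeds <- .substreams(config$seed, 2L * config$n_iterations + 1L)
  # one fixed patient-level permutation per shadow column (persistent under
  # both patient subsampling and duplicate re-choice)
  sigma <- withr::with_seed(seeds[1L],
    vapply(seq_len(n_ratio), function(j) sample.int(n_pat), integer(n_pat)))
  pair_idx <- NULL
  thr <- config$importance_threshold_fraction

  for (i in seq_len(config$n_iterations)) {
    s <- seeds[(2L * (i - 1L) + 2L):(2L * i + 1L)]
    ch <- withr::with_seed(s[1L], {
      # one randomly chosen duplicate per patient, then the class-wise pool
      row_of <- vapply(pats, function(pt) {
        ss <- samples_of[[pt]]
        if (length(ss) > 1L) sample(ss, 1L) else ss
      }, character(1L))
      list(row_of = row_of,
           pool = .subsample_patients(samples_of, lab_patient, config))
    })
    rows <- ch$row_of[ch$pool]
    full <- imputeMissing(m, seed = s[2L])
    lr <- expandLogRatios(full)
    if (is.null(pair_idx)) pair_idx <- pairIndex(lr)
    all_ratios <- ratioValues(lr)
    ridx <- match(rows, rownames(m))
    pidx <- match(ch$pool, pats)
    real <- all_ratios[ridx, , drop = FALSE]
    shadow <- vapply(seq_len(n_ratio), function(j)
      all_ratios[match(ch$row_of[sigma[pidx, j]], rownames(m)), j],
      numeric(length(ridx)))
    colnames(shadow) <- paste0("shadow_", seq_len(n_ratio))
    z <- cbind(real, shadow)
    rownames(z) <- rows
    y <- droplevels(lab_sample[rows])
    fit <- withr::with_seed(s[1L], randomForest::randomForest(
      z, y, ntree = config$rf_trees, importance = TRUE))
    imp <- randomForest::importance(fit, type = 1L, scale = FALSE)[, 1L]
    mx <- max(imp)
    if (mx <= 0) next  # no informative split this iteration: no hits
    hits <- imp >= thr * mx
    hit_real <- hit_real + hits[seq_len(n_ratio)]
    hit_shadow <- hit_shadow + hits[n_ratio + seq_len(n_ratio)]
  }

  freq <- hit_real / config$n_iterations
  shadow_max <- max(hit_shadow) / config$n_iterations
  freq[freq <= shadow_max] <- 0
  sq <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
  sq[cbind(pair_idx$num_index, pair_idx$den_index)] <- freq
  sq[cbind(pair_idx$den_index, pair_idx$num_index)] <- freq
  new("ImportanceFrequencyMatrix", freq = sq, shadowMax = shadow_max,
      columnScores = colSums(sq), nIterations = config$n_iterations)
}

#' Rank compounds and optimise the selected feature set
#'
#' Compounds are ranked by their column scores in the thresholded
#' importance-frequency matrix. For each candidate size k, the surviving
#' ratios connected to the top-k compounds form a candidate model, evaluated
#' by duplicate-safe internal-validation AUC; the k maximising the mean AUC
#' is returned (ties broken toward the smallest k).
#'
#' @param freq an [ImportanceFrequencyMatrix-class].
#' @param x,labeling,config as in [importanceFrequency()].
#' @param n_eval internal-validation iterations per candidate size.
#' @param max_k cap on the number of candidate sizes examined.
#' @return list with `selected_features`, `selected_ratios` (data.frame
#'   `num`/`den`), `k`, and `auc_table`.
#' @export
rankAndOptimize <- function(freq, x, labeling, config = selectionConfig(),
                            n_eval = 8L, max_k = NULL) {
  stopifnot(is(freq, "ImportanceFrequencyMatrix"))
  cs <- columnScores(freq)
  if (all(cs == 0)) {
    warning("no ratio survived shadow thresholding; empty selection")
    return(list(selected_features = character(0),
                selected_ratios = data.frame(num = character(0),
                                             den = character(0)),
                k = 0L,
                auc_table = data.frame(k = integer(0),
                                       mean_auc = numeric(0))))
  }
  fm <- freqMatrix(freq)
  feats <- colnames(fm)
  ord <- order(cs, decreasing = TRUE)
  K <- sum(cs > 0)
  if (!is.null(max_k)) K <- min(K, max_k)
  ut <- which(upper.tri(fm) & fm > 0, arr.ind = TRUE)
  surviving <- data.frame(num = feats[ut[, 1L]], den = feats[ut[, 2L]],
                          num_index = ut[, 1L], den_index = ut[, 2L],
                          stringsAsFactors = FALSE)

  x <- subsetByRole(x, "biological")
  if (!is(labeling, "BinaryLabeling")) labeling <- mergePscGroups(x)
  m <- intensities(x)
  lab_sample <- classLabels(labeling)
  lab_patient <- tapply(as.character(labeling@labels),
                        labeling@patientIds, function(v) v[1L])
  samples_of <- split(labeling@sampleIds, labeling@patientIds)
  seeds <- .substreams(config$seed + 1L, 2L * n_eval)

  eval_ratios <- function(pairs) {
    aucs <- numeric(n_eval)
    for (e in seq_len(n_eval)) {
      s <- seeds[(2L * (e - 1L) + 1L):(2L * e)]
      pool <- withr::with_seed(s[1L],
        .subsample_patients(samples_of, lab_patient, config))
      full <- imputeMissing(m, seed = s[2L])
      z <- ratioColumns(full, pairs)
      train <- unlist(samples_of[pool], use.names = FALSE)
      test <- setdiff(rownames(m), train)
      y_tr <- droplevels(lab_sample[train])
      if (nlevels(y_tr) < 2L || length(test) == 0L) {
        aucs[e] <- NA_real_
        next
      }
      fit <- withr::with_seed(s[1L], randomForest::randomForest(
        z[train, , drop = FALSE], y_tr, ntree = config$rf_trees))
      pr <- stats::predict(fit, z[test, , drop = FALSE],
                           type = "prob")[, "PSC"]
      aucs[e] <- .auc_fast(pr, lab_sample[test])
    }
    mean(aucs, na.rm = TRUE)
  }

  # candidate model for top-k: the surviving ratios among the top-k
  # compounds; when none lie fully inside the set (degenerate matrices),
  # fall back to the surviving ratios connected to it
  ratios_for <- function(top) {
    pairs <- surviving[surviving$num %in% top & surviving$den %in% top,
                       c("num", "den"), drop = FALSE]
    if (nrow(pairs) == 0L)
      pairs <- surviving[surviving$num %in% top | surviving$den %in% top,
                         c("num", "den"), drop = FALSE]
    pairs
  }
  ks <- seq_len(K)
  mean_auc <- vapply(ks, function(k) {
    pairs <- ratios_for(feats[ord[seq_len(k)]])
    if (nrow(pairs) == 0L) return(NA_real_)
    eval_ratios(pairs)
  }, numeric(1L))
  best <- ks[which.max(round(mean_auc, 10))]  # which.max takes the first max
  top <- feats[ord[seq_len(best)]]
  pairs <- ratios_for(top)
  rownames(pairs) <- NULL
  list(selected_features = top, selected_ratios = pairs, k = best,
       auc_table = data.frame(k = ks, mean_auc = mean_auc))
}
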