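#' Blank-based feature retention for headspace tables
#'
#' A feature is considered to truly originate from the fecal headspace — and
#' is retained — if and only if its median over biological samples strictly
#' exceeds its median over microchamber blanks plus three times the
#' interquartile range over microchamber blanks. Instrument blanks and QC
#' samples take no part in the rule (QC monitors instrument performance
#' only). Missing entries are excluded from the order statistics; a feature
#' missing in all biological samples is dropped with reason `"all-missing"`.
#' The IQR uses linear-interpolation quantiles (R type 7), recorded in the
#' result so the convention is pinned.
#'
#' @param x a [VOCExperiment-class] containing at least one biological sample
#'   and at least two microchamber blanks.
#' @return a [BlankFilterResult-class].
#' @export
blankFilter <- function(x) {
  sd <- sampleData(x)
  bio <- sd$role == "biological"
  blk <- sd$role == "mc_blank"
  if (sum(bio) < 1L)
    stop("blank filter requires at least one biological sample")
  if (sum(blk) < 2L)
    stop("blank filter requires at least two microchamber blanks")
  m <- intensities(x)
  feats <- colnames(m)
  sample_med <- apply(m[bio, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  blank_med <- apply(m[blk, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  blank_iqr <- apply(m[blk, , drop = FALSE], 2, stats::IQR,
                     na.rm = TRUE, type = 7)
  threshold <- blank_med + 3 * blank_iqr
  all_missing <- apply(m[bio, , drop = FALSE], 2,
                       function(v) all(is.na(v)))
  kept <- !all_missing & !is.nan(sample_med) & sample_med > threshold
  pf <- data.frame(
    feature = feats,
    sample_median = ifelse(all_missing, NA_real_, sample_med),
    blank_median = blank_med, blank_iqr = blank_iqr,
    threshold = threshold, kept = kept,
    reason = ifelse(all_missing, "all-missing",
                    ifelse(kept, "kept", "below-threshold")),
    row.names = NULL, stringsAsFactors = FALSE)
  new("BlankFilterResult", retained = feats[kept], perFeature = pf,
      quantileType = 7L)
}

#' Unsupervised Random-Forest screen for batch effects and true signal
#'
#' Trains a Breiman-style unsupervised Random Forest: the real rows are
#' contrasted against a synthetic copy in which every column is permuted
#' independently, destroying the joint structure while preserving marginals.
#' Pairwise proximities among the real samples, their principal-coordinate
#' embedding and the silhouette of biological samples against blanks are
#' returned; a clear biological/blank separation confirms the analysis rests
#' on signal truly coming from the samples.
#'
#' @param x a [VOCExperiment-class] with at least three samples. Missing
#'   entries are filled with feature medians for the screen only.
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return list with `proximity` ([ProximityMatrix-class]), `coordinates`
#'   (n x 2 PCoA embedding), `silhouette` (the blank/biological separation
#'   score: mean silhouette width of the blank samples against the
#'   biological group, `NA` if only one role group — biological profiles are
#'   internally heterogeneous, so the blank side is where separation shows)
#'   and `cluster_report` (per-sample role and silhouette width).
#' @export
unsupervisedRFScreen <- function(x, seed = 1L, ntree = 500L) {
  m <- intensities(x)
  n <- nrow(m)
  if (n < 3L) stop("unsupervised screen requires at least 3 samples")
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (anyNA(v)) m[is.na(v), j] <- stats::median(v, na.rm = TRUE)
  }
  if (all(apply(m, 2, stats::sd) == 0)) stop("no variation in the table")
  withr::with_seed(as.integer(seed), {
    synth <- apply(m, 2, sample)
    z <- rbind(m, synth)
    y <- factor(rep(c("real", "synthetic"), each = n))
    fit <- randomForest::randomForest(z, y, ntree = ntree, proximity = TRUE)
  })
  prox <- .new_proximity(fit$proximity[seq_len(n), seq_len(n)], rownames(m))
  emb <- proximityPCoA(prox, k = 2L)
  sd <- sampleData(x)
  grp <- ifelse(sd$role == "biological", "biological", "blank")
  sil_mean <- NA_real_
  rep_df <- data.frame(sample_id = rownames(m), role = sd$role,
                       silhouette = NA_real_, stringsAsFactors = FALSE)
  if (length(unique(grp)) == 2L) {
    sil <- cluster::silhouette(as.integer(factor(grp)),
                               stats::as.dist(1 - proximity(prox)))
    rep_df$silhouette <- sil[, "sil_width"]
    sil_mean <- mean(sil[grp == "blank", "sil_width"])
  }
  list(proximity = prox, coordinates = emb$coordinates,
       silhouette = sil_mean, cluster_report = rep_df)
}

#' Principal-coordinate embedding of a proximity matrix
#'
#' Classical multidimensional scaling of the dissimilarity `1 - proximity`.
#' Negative eigenvalues (the dissimilarity need not be Euclidean) are
#' truncated to zero.
#'
#' @param prox a [ProximityMatrix-class] or symmetric similarity matrix.
#' @param k number of coordinates to return.
#' @return list with `coordinates` (n x k), `eigenvalues` (all, before
#'   truncation) and `variance_explained` (per returned axis, as a fraction
#'   of the positive eigenvalue mass).
#' @export
proximityPCoA <- function(prox, k = 2L) {
  v <- if (is(prox, "ProximityMatrix")) proximity(prox) else as.matrix(prox)
  d <- stats::as.dist(1 - v)
  n <- nrow(v)
  fit <- suppressWarnings(
    stats::cmdscale(d, k = max(1L, min(k, n - 1L)), eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k)  # degenerate geometry: pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  pos <- pmax(fit$eig, 0)
  ve <- if (sum(pos) > 0) pos[seq_len(k)] / sum(pos) else rep(0, k)
  rownames(pts) <- rownames(v)
  list(coordinates = pts[, seq_len(k), drop = FALSE],
       eigenvalues = fit$eig, variance_explained = ve)
}
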