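#' Random imputation of missing intensities
#'
#' Each missing entry of a feature is replaced by a uniform draw from
#' `[0.5 * m_f, m_f]`, where `m_f` is the feature's minimum observed positive
#' value — the conventional below-detection-limit treatment for volatolomics
#' tables. The draw is seeded; repeated calls with the same seed reproduce
#' the imputation exactly, and downstream procedures that repeat the
#' imputation (stability selection, iterated correlation) derive one sub-seed
#' per iteration.
#'
#' @param x a samples-by-features numeric matrix with `NA` for missing
#'   entries, or a [VOCExperiment-class] (its intensity matrix is used).
#' @param seed integer seed.
#' @return a complete, strictly positive matrix of the same shape.
#' @export
imputeMissing <- function(x, seed = 1L) {
  m <- if (is(x, "VOCExperiment")) intensities(x) else as.matrix(x)
  if (!anyNA(m)) return(m)
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      miss <- is.na(v)
      if (!any(miss)) next
      obs <- v[!miss & v > 0]
      if (length(obs) == 0L)
        stop("feature '", colnames(m)[j],
             "' has no observed positive value; drop it upstream")
      mf <- min(obs)
      m[miss, j] <- stats::runif(sum(miss), 0.5 * mf, mf)
    }
    m
  })
}

#' Expand a positive matrix into all pairwise log ratios
#'
#' For p features, all p(p-1)/2 unordered pairs are formed in canonical
#' orientation (numerator index < denominator index) and the natural log of
#' the within-sample quotient is taken. Multiplying a sample row by any
#' positive constant leaves its ratio row unchanged, which is what removes
#' per-sample dilution (size) effects without normalisation.
#'
#' @param m strictly positive samples-by-features matrix with column names.
#' @return a [LogRatioMatrix-class].
#' @export
expandLogRatios <- function(m) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) stop("feature names are required")
  if (anyNA(m) || any(m <= 0))
    stop("log-ratio expansion requires a complete, strictly positive matrix")
  p <- ncol(m)
  if (p < 2L) stop("at least two features are required")
  pairs <- utils::combn(p, 2L)
  vals <- log(m[, pairs[1L, ], drop = FALSE] / m[, pairs[2L, ], drop = FALSE])
  idx <- data.frame(
    num_index = pairs[1L, ], den_index = pairs[2L, ],
    num = colnames(m)[pairs[1L, ]], den = colnames(m)[pairs[2L, ]],
    stringsAsFactors = FALSE)
  idx$ratio <- paste(idx$num, idx$den, sep = "/")
  colnames(vals) <- idx$ratio
  rownames(vals) <- rownames(m)
  new("LogRatioMatrix", values = vals, pairIndex = idx)
}

#' Compute selected log-ratio columns directly
#'
#' Avoids materialising the full p(p-1)/2 expansion when only an optimised
#' subset of ratios is needed.
#'
#' @param m strictly positive samples-by-features matrix.
#' @param pairs data.frame with columns `num` and `den` (compound names).
#' @return samples-by-ratios matrix.
#' @export
ratioColumns <- function(m, pairs) {
  m <- as.matrix(m)
  miss <- setdiff(unique(c(pairs$num, pairs$den)), colnames(m))
  if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  if (anyNA(m) || any(m <= 0))
    stop("log ratios require a complete, strictly positive matrix")
  out <- log(m[, pairs$num, drop = FALSE] / m[, pairs$den, drop = FALSE])
  colnames(out) <- paste(pairs$num, pairs$den, sep = "/")
  out
}

#' Shadow features: column-wise row permutations
#'
#' Each shadow column is an independent permutation of the rows of the
#' corresponding real column, preserving every marginal distribution while
#' destroying any association with the class labels. The maximum selection
#' frequency attained by a shadow feature serves as the data-driven null
#' threshold in stability selection.
#'
#' @param m numeric matrix with at least two rows.
#' @param seed integer seed.
#' @return matrix of the same shape with columns prefixed `"shadow_"`.
#' @export
makeShadow <- function(m, seed = 1L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("shadow features require at least two rows")
  withr::with_seed(as.integer(seed), {
    sh <- apply(m, 2, sample)
  })
  colnames(sh) <- paste0("shadow_", seq_len(ncol(m)))
  rownames(sh) <- rownames(m)
  sh
}

#' Sampler of imputed log-ratio columns for iterated analyses
#'
#' Returns a `function(seed)` producing one random imputation of the raw
#' table followed by computation of the selected ratio columns — the unit of
#' iteration for the cross-platform correlation procedure.
#'
#' @param x a [VOCExperiment-class] (biological samples are used).
#' @param pairs data.frame of ratio pairs (`num`, `den`).
#' @param samples optional sample ids to restrict to.
#' @return function mapping an integer seed to a samples-by-ratios matrix.
#' @export
ratioSampler <- function(x, pairs, samples = NULL) {
  m <- intensities(subsetByRole(x, "biological"))
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  force(pairs)
  function(seed) ratioColumns(imputeMissing(m, seed), pairs)
}
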