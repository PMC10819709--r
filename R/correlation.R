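#' Configuration for the iterated cross-platform correlation procedure
#'
#' The study runs 5000 iterations with an equal number of random
#' imputations and a significance level of 0.05; the permutation count per
#' canonical-correlation test is a package choice.
#'
#' @param n_iterations imputation iterations.
#' @param alpha significance level.
#' @param n_permutations permutations per canonical significance test.
#' @param seed integer root seed.
#' @export
correlationConfig <- function(n_iterations = 5000L, alpha = 0.05,
                              n_permutations = 199L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(n_iterations = .check_count(n_iterations, "n_iterations", 1L),
                 alpha = alpha,
                 n_permutations = .check_count(n_permutations,
                                               "n_permutations", 19L),
                 seed = .check_count(seed, "seed", 0L)),
            class = "CorrelationConfig")
}

.standardize <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 2, stats::sd)
  if (any(s == 0)) s[s == 0] <- 1
  scale(m, scale = s)
}

# First canonical correlation; ridge-regularised fallback for
# rank-deficient inputs.
.cca_core <- function(X, Y) {
  r <- tryCatch({
    cc <- stats::cancor(X, Y)
    # cancor silently drops collinear columns; treat that as rank deficiency
    if (nrow(cc$xcoef) != ncol(X) || nrow(cc$ycoef) != ncol(Y) ||
        length(cc$cor) == 0L) NULL
    else list(r1 = cc$cor[1L], xcoef = cc$xcoef[, 1L],
              ycoef = cc$ycoef[, 1L], ridge = FALSE)
  }, error = function(e) NULL)
  if (!is.null(r)) return(r)
  lam <- 1e-3
  Sxx <- stats::cov(X) + lam * diag(ncol(X))
  Syy <- stats::cov(Y) + lam * diag(ncol(Y))
  Sxy <- stats::cov(X, Y)
  ex <- eigen(Sxx, symmetric = TRUE)
  ey <- eigen(Syy, symmetric = TRUE)
  isqrt <- function(e) e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                          length(e$values)) %*% t(e$vectors)
  K <- isqrt(ex) %*% Sxy %*% isqrt(ey)
  sv <- svd(K)
  list(r1 = min(1, sv$d[1L]),
       xcoef = drop(isqrt(ex) %*% sv$u[, 1L]),
       ycoef = drop(isqrt(ey) %*% sv$v[, 1L]),
       ridge = TRUE)
}

#' First canonical variate with a permutation significance test
#'
#' Finds the maximally correlated linear combinations of two column-wise
#' standardised matrices and assesses significance by permuting the row
#' order of `Y`. Structure loadings (correlations of each variable with its
#' side's first canonical variate) are returned for recursive feature
#' elimination. Rank-deficient inputs fall back to a ridge-regularised CCA
#' with a warning.
#'
#' @param X,Y numeric matrices over the same samples.
#' @param n_permutations permutation count for the p-value.
#' @param seed integer seed.
#' @return list with `r1`, `loadings_x`, `loadings_y`, `p_value`.
#' @export
ccaFirstVariate <- function(X, Y, n_permutations = 199L, seed = 1L) {
  X <- .standardize(X); Y <- .standardize(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must share samples")
  if (n <= max(ncol(X), ncol(Y)) + 2L)
    warning("sample size is small relative to dimensionality; ",
            "canonical correlations will be inflated")
  cc <- .cca_core(X, Y)
  if (cc$ridge) warning("rank deficiency: ridge-regularised CCA used")
  u <- drop(X %*% cc$xcoef)
  v <- drop(Y %*% cc$ycoef)
  lx <- drop(stats::cor(X, u)); names(lx) <- colnames(X)
  ly <- drop(stats::cor(Y, v)); names(ly) <- colnames(Y)
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(b) {
      suppressWarnings(.cca_core(X, Y[sample.int(n), , drop = FALSE])$r1)
    }, numeric(1L))
  })
  p <- (1 + sum(perm >= cc$r1)) / (1 + n_permutations)
  list(r1 = cc$r1, loadings_x = lx, loadings_y = ly, p_value = p)
}

#' Recursive feature elimination until canonical significance
#'
#' Repeatedly drops the feature (from either platform) with the smallest
#' absolute structure loading on the first canonical variate, re-fitting
#' after each drop, until the permutation p-value reaches `alpha` or at
#' most two features remain per side. When significance is never reached,
#' the minimal surviving set is returned flagged non-significant.
#'
#' @param X,Y numeric matrices over the same samples.
#' @param config a [correlationConfig()].
#' @param seed seed for the permutation tests (defaults to `config$seed`).
#' @return list with `selected_x`, `selected_y`, `r1`, `p`, `significant`,
#'   `n_dropped`.
#' @export
rfeToSignificance <- function(X, Y, config = correlationConfig(),
                              seed = config$seed) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  seeds <- .substreams(seed, ncol(X) + ncol(Y) + 1L)
  step <- 0L
  repeat {
    step <- step + 1L
    cc <- suppressWarnings(
      ccaFirstVariate(X, Y, config$n_permutations, seeds[step]))
    if (cc$p_value <= config$alpha)
      return(list(selected_x = colnames(X), selected_y = colnames(Y),
                  r1 = cc$r1, p = cc$p_value, significant = TRUE,
                  n_dropped = step - 1L))
    drop_x <- ncol(X) > 2L
    drop_y <- ncol(Y) > 2L
    if (!drop_x && !drop_y)
      return(list(selected_x = colnames(X), selected_y = colnames(Y),
                  r1 = cc$r1, p = cc$p_value, significant = FALSE,
                  n_dropped = step - 1L))
    lx <- if (drop_x) abs(cc$loadings_x) else NULL
    ly <- if (drop_y) abs(cc$loadings_y) else NULL
    cand <- c(lx, ly)
    worst <- names(cand)[which.min(cand)]
    if (!is.null(lx) && worst %in% colnames(X))
      X <- X[, colnames(X) != worst, drop = FALSE]
    else
      Y <- Y[, colnames(Y) != worst, drop = FALSE]
  }
}

#' Permutation screening of cross-platform features
#'
#' Runs [rfeToSignificance()] across `n_iterations` imputations of the real
#' data and, in parallel, of data in which the rows of `Y` are permuted
#' (breaking the cross-platform link while preserving both marginal
#' structures). Features selected significantly more often in the real than
#' in the permuted runs — by a chi-square test on the 2x2 selection table
#' with Yates continuity correction — are screened in.
#'
#' @param X,Y numeric matrices, or sampler functions `function(seed)`
#'   returning one imputation of the platform (used for the multiply-imputed
#'   fecal side).
#' @param config a [correlationConfig()].
#' @return list with `selected_x`, `selected_y` and `counts` (per-feature
#'   selection counts and screening p-values).
#' @export
permutationScreen <- function(X, Y, config = correlationConfig()) {
  if (config$n_iterations < 2L)
    stop("insufficient iterations for screening (need at least 2)")
  seeds <- .substreams(config$seed, 4L * config$n_iterations)
  x0 <- .draw_matrix(X, seeds[1L]); y0 <- .draw_matrix(Y, seeds[1L])
  xn <- colnames(x0) %||% paste0("x", seq_len(ncol(x0)))
  yn <- colnames(y0) %||% paste0("y", seq_len(ncol(y0)))
  cnt <- matrix(0L, nrow = length(c(xn, yn)), ncol = 2L,
                dimnames = list(c(xn, yn), c("real", "permuted")))
  side <- rep(c("x", "y"), c(length(xn), length(yn)))
  for (i in seq_len(config$n_iterations)) {
    s <- seeds[(4L * (i - 1L) + 1L):(4L * i)]
    Xi <- .draw_matrix(X, s[1L]); Yi <- .draw_matrix(Y, s[2L])
    colnames(Xi) <- xn; colnames(Yi) <- yn
    real <- rfeToSignificance(Xi, Yi, config, seed = s[3L])
    if (real$significant)
      cnt[c(real$selected_x, real$selected_y), "real"] <-
        cnt[c(real$selected_x, real$selected_y), "real"] + 1L
    Yp <- withr::with_seed(s[4L], Yi[sample.int(nrow(Yi)), , drop = FALSE])
    perm <- rfeToSignificance(Xi, Yp, config, seed = s[3L])
    if (perm$significant)
      cnt[c(perm$selected_x, perm$selected_y), "permuted"] <-
        cnt[c(perm$selected_x, perm$selected_y), "permuted"] + 1L
  }
  n <- config$n_iterations
  pvals <- apply(cnt, 1L, function(row) {
    tab <- rbind(c(row["real"], n - row["real"]),
                 c(row["permuted"], n - row["permuted"]))
    if (all(tab[, 1L] == 0) || all(tab[, 2L] == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  })
  keep <- pvals < config$alpha & cnt[, "real"] > cnt[, "permuted"]
  list(selected_x = xn[keep[side == "x"]],
       selected_y = yn[keep[side == "y"]],
       counts = data.frame(feature = rownames(cnt), side = side,
                           real = cnt[, "real"], permuted = cnt[, "permuted"],
                           p = pvals, screened = keep, row.names = NULL))
}

#' Fisher-z average of correlation coefficients
#'
#' Correlations are averaged on the `atanh` scale and transformed back; the
#' average of identical values is exactly that value, and the result is
#' invariant to the order of iterations.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return the z-averaged correlation.
#' @export
fisherZMean <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0L) return(NA_real_)
  tanh(mean(atanh(r)))
}

#' Averaged multivariate and univariate cross-platform correlations
#'
#' Across `n_iterations` imputations, computes the first canonical
#' correlation (with its permutation p-value) and all univariate Pearson
#' correlations between the screened feature sets, then averages all
#' correlations via the Fisher z-transform. The fraction of iterations
#' whose canonical p-value falls below `alpha` is reported; univariate
#' p-values (from the t-distribution of the averaged correlation) are
#' Benjamini-Hochberg adjusted within the screened matrix.
#'
#' @param X,Y matrices or sampler functions as in [permutationScreen()].
#' @param selected_x,selected_y screened feature sets (non-empty).
#' @param config a [correlationConfig()].
#' @return a [CorrelationResult-class].
#' @export
averagedCorrelations <- function(X, Y, selected_x, selected_y,
                                 config = correlationConfig()) {
  if (length(selected_x) == 0L || length(selected_y) == 0L)
    stop("screened feature sets must be non-empty")
  seeds <- .substreams(config$seed + 7L, 3L * config$n_iterations)
  r1s <- ps <- numeric(config$n_iterations)
  usum <- matrix(0, length(selected_x), length(selected_y),
                 dimnames = list(selected_x, selected_y))
  n_samp <- NA_integer_
  for (i in seq_len(config$n_iterations)) {
    s <- seeds[(3L * (i - 1L) + 1L):(3L * i)]
    Xi <- .draw_matrix(X, s[1L])[, selected_x, drop = FALSE]
    Yi <- .draw_matrix(Y, s[2L])[, selected_y, drop = FALSE]
    n_samp <- nrow(Xi)
    cc <- suppressWarnings(
      ccaFirstVariate(Xi, Yi, config$n_permutations, s[3L]))
    r1s[i] <- cc$r1
    ps[i] <- cc$p_value
    usum <- usum + atanh(pmin(1 - 1e-12,
                              pmax(-1 + 1e-12, stats::cor(Xi, Yi))))
  }
  uz <- tanh(usum / config$n_iterations)
  tt <- abs(uz) * sqrt((n_samp - 2) / pmax(1e-12, 1 - uz^2))
  up <- 2 * stats::pt(tt, df = n_samp - 2, lower.tail = FALSE)
  uni <- data.frame(
    x = rep(selected_x, times = length(selected_y)),
    y = rep(selected_y, each = length(selected_x)),
    r = as.vector(uz), p = as.vector(up),
    p_adj = stats::p.adjust(as.vector(up), method = "BH"),
    stringsAsFactors = FALSE)
  new("CorrelationResult",
      selectedX = as.character(selected_x),
      selectedY = as.character(selected_y),
      canonicalR = fisherZMean(r1s), meanP = mean(ps),
      fracSignificant = mean(ps < config$alpha), univariate = uni,
      significant = mean(ps) <= config$alpha,
      nIterations = config$n_iterations)
}

#' Association of a VOC platform with blood markers of liver disease
#'
#' Restricted to the positive (PSC-class) population, where the blood
#' parameters are expected to vary meaningfully: constant blood columns are
#' dropped with a warning, the permutation screen is run with the blood
#' matrix as the second platform, and the averaged correlations are
#' computed on the screened sets (falling back to the full sets, flagged,
#' when nothing screens in).
#'
#' @param platform matrix or sampler function for the VOC side (rows:
#'   positive-class patients).
#' @param blood numeric matrix of blood markers (ALP, AST, ALT, bilirubin)
#'   for the same patients.
#' @param config a [correlationConfig()].
#' @return a [CorrelationResult-class].
#' @export
bloodAssociation <- function(platform, blood, config = correlationConfig()) {
  blood <- as.matrix(blood)
  if (sum(stats::complete.cases(blood)) < 6L)
    stop("fewer than 6 patients with complete blood data")
  keep <- stats::complete.cases(blood)
  blood <- blood[keep, , drop = FALSE]
  platform <- if (is.function(platform)) {
    pf <- platform
    function(seed) pf(seed)[keep, , drop = FALSE]
  } else as.matrix(platform)[keep, , drop = FALSE]
  const <- apply(blood, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant blood column(s): ",
            paste(colnames(blood)[const], collapse = ", "))
    blood <- blood[, !const, drop = FALSE]
  }
  scr <- permutationScreen(platform, blood, config)
  sel_x <- scr$selected_x
  sel_y <- scr$selected_y
  fallback <- length(sel_x) == 0L || length(sel_y) == 0L
  if (fallback) {
    x0 <- .draw_matrix(platform, config$seed)
    sel_x <- colnames(x0) %||% paste0("x", seq_len(ncol(x0)))
    sel_y <- colnames(blood)
  }
  res <- averagedCorrelations(platform, blood, sel_x, sel_y, config)
  if (fallback) res@significant <- FALSE
  res
}
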