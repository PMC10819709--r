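# Shared fixtures and independent oracles, all built in code.

# Small synthetic cohort defaults used across the suite: the study's group
# proportions at reduced patient and feature counts so single tests stay fast.
small_sim <- function(seed = 1, ...) {
  args <- list(seed = seed, n_psc = 4, n_psc_ibd = 6, n_ibd = 14,
               n_features_fecal = 10, n_features_breath = 8, n_markers = 3,
               missing_rate = 0.08, n_mc_blanks = 4, n_instrument_blanks = 2)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

# Hand-built table: 3 biological + 4 microchamber blanks, 2 features.
tiny_experiment <- function(values = NULL) {
  if (is.null(values))
    values <- matrix(c(5, 6, 7, 10, 11, 12), nrow = 3,
                     dimnames = list(NULL, c("phenol", "styrene")))
  n_bio <- nrow(values)
  blanks <- matrix(0.1, 4, ncol(values),
                   dimnames = list(NULL, colnames(values)))
  meta <- data.frame(
    sample_id = c(sprintf("S%d", seq_len(n_bio)), sprintf("B%d", 1:4)),
    patient_id = c(sprintf("P%d", seq_len(n_bio)), sprintf("B%d", 1:4)),
    group = c(rep(c("PSC", "IBD"), length.out = n_bio), rep(NA, 4)),
    role = c(rep("biological", n_bio), rep("mc_blank", 4)),
    duplicate_index = 1L, stringsAsFactors = FALSE)
  VOCExperiment(rbind(values, blanks), meta)
}

# Independent brute-force oracle for the blank retention rule: quantiles
# recomputed from sorted values by explicit linear interpolation.
oracle_quantile <- function(v, q) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n == 0) return(NA_real_)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_blank_filter <- function(values, roles) {
  bio <- roles == "biological"
  blk <- roles == "mc_blank"
  kept <- logical(ncol(values))
  for (j in seq_len(ncol(values))) {
    b <- values[bio, j]
    if (all(is.na(b))) { kept[j] <- FALSE; next }
    sm <- oracle_quantile(b, 0.5)
    bm <- oracle_quantile(values[blk, j], 0.5)
    iqr <- oracle_quantile(values[blk, j], 0.75) -
      oracle_quantile(values[blk, j], 0.25)
    kept[j] <- sm > bm + 3 * iqr
  }
  colnames(values)[kept]
}

# Exhaustive concordant-pair AUC (ties counted half).
oracle_auc_pairs <- function(probs, labels) {
  pos <- which(labels == "PSC")
  neg <- which(labels == "IBD")
  conc <- 0
  for (i in pos) for (j in neg)
    conc <- conc + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
  conc / (length(pos) * length(neg))
}

# Random power-of-two row scalings: exact in floating point, so log ratios
# are bitwise invariant.
pow2_scale_rows <- function(m, seed) {
  withr::with_seed(seed, {
    f <- 2^sample(-5:5, nrow(m), replace = TRUE)
  })
  m * f
}
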