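#' Configuration for the synthetic two-platform cohort generator
#'
#' Defaults reproduce the structure of the study cohort: 8 PSC, 16 PSC/IBD
#' and 49 IBD patients; fecal headspace measured mostly in duplicate (67 of
#' 73 patients, rate 0.92); the 62-compound targeted fecal panel and the
#' 20-compound breath panel; group mean fecal water contents 74.02 / 80.33 /
#' 73.79 percent. Where the study reports no value (noise magnitudes,
#' missingness, blank counts) the defaults are conventional choices for
#' headspace GC-MS volatolomics, documented in the methods vignette.
#'
#' @param seed integer root seed for the cohort.
#' @param n_psc,n_psc_ibd,n_ibd patient counts per group.
#' @param duplicate_rate probability a patient's fecal sample is measured
#'   twice.
#' @param n_features_fecal,n_features_breath feature counts per platform;
#'   when they equal the packaged panel sizes (62, 20) the packaged compound
#'   names are used.
#' @param n_markers planted discriminatory VOCs per platform.
#' @param effect_size mean log-fold shift of planted markers in the positive
#'   class (natural-log scale).
#' @param dilution_sd standard deviation of the per-sample multiplicative
#'   log-scale dilution factor (fecal platform; the curated breath table is
#'   taken as already normalised).
#' @param missing_rate fraction of fecal biological entries set missing,
#'   biased toward low intensities (detection-limit censoring).
#' @param n_mc_blanks,n_instrument_blanks blank sample counts.
#' @param blank_leak fraction of fecal features also present in blanks at a
#'   sample-comparable level (so the blank-retention rule removes them).
#' @param water_mean_by_group,water_sd fecal water-content distribution
#'   (percent), truncated to `[0, 100]`.
#' @param blood_link_strength correlation between (log) blood markers and the
#'   latent breath-marker signal.
#' @param bio_sd,meas_sd patient-level biological and within-duplicate
#'   measurement noise standard deviations (log scale).
#' @param feature_log_mean,feature_log_sd distribution of per-feature
#'   baseline log intensities.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_psc = 8L, n_psc_ibd = 16L, n_ibd = 49L,
                             duplicate_rate = 0.92,
                             n_features_fecal = 62L,
                             n_features_breath = 20L,
                             n_markers = 6L,
                             effect_size = 0.8,
                             dilution_sd = 1.0,
                             missing_rate = 0.10,
                             n_mc_blanks = 8L,
                             n_instrument_blanks = 4L,
                             blank_leak = 0.10,
                             water_mean_by_group = c(PSC = 74.02,
                                                     PSC_IBD = 80.33,
                                                     IBD = 73.79),
                             water_sd = 5,
                             blood_link_strength = 0.9,
                             bio_sd = 0.5, meas_sd = 0.25,
                             feature_log_mean = 9, feature_log_sd = 1) {
  cfg <- list(seed = .check_count(seed, "seed", 0L),
              n_psc = .check_count(n_psc, "n_psc"),
              n_psc_ibd = .check_count(n_psc_ibd, "n_psc_ibd"),
              n_ibd = .check_count(n_ibd, "n_ibd"),
              duplicate_rate = .check_fraction(duplicate_rate,
                                              "duplicate_rate", FALSE),
              n_features_fecal = .check_count(n_features_fecal,
                                              "n_features_fecal", 2L),
              n_features_breath = .check_count(n_features_breath,
                                               "n_features_breath", 2L),
              n_markers = .check_count(n_markers, "n_markers"),
              effect_size = effect_size,
              dilution_sd = dilution_sd,
              missing_rate = .check_fraction(missing_rate, "missing_rate",
                                             FALSE),
              n_mc_blanks = .check_count(n_mc_blanks, "n_mc_blanks"),
              n_instrument_blanks = .check_count(n_instrument_blanks,
                                                 "n_instrument_blanks"),
              blank_leak = .check_fraction(blank_leak, "blank_leak", FALSE),
              water_mean_by_group = water_mean_by_group,
              water_sd = water_sd,
              blood_link_strength = .check_fraction(blood_link_strength,
                                                    "blood_link_strength",
                                                    FALSE),
              bio_sd = bio_sd, meas_sd = meas_sd,
              feature_log_mean = feature_log_mean,
              feature_log_sd = feature_log_sd)
  if (cfg$dilution_sd < 0) stop("'dilution_sd' must be >= 0")
  if (cfg$n_markers > min(cfg$n_features_fecal, cfg$n_features_breath))
    stop("n_markers exceeds the number of features on a platform")
  structure(cfg, class = "SimulationConfig")
}

.feature_names <- function(platform, p) {
  panel <- packagedPanel(platform)
  if (p == length(compounds(panel))) return(compounds(panel))
  sprintf("%s_voc_%02d", platform, seq_len(p))
}

# Patient-level latent log-intensities: baseline + planted class shift +
# patient biological noise (shared between duplicates).
.patient_signal <- function(n_feat, positive, markers, signs, cfg) {
  mu <- stats::rnorm(n_feat, cfg$feature_log_mean, cfg$feature_log_sd)
  n_pat <- length(positive)
  theta <- matrix(rep(mu, each = n_pat), nrow = n_pat) +
    matrix(stats::rnorm(n_pat * n_feat, 0, cfg$bio_sd), nrow = n_pat)
  if (length(markers))
    theta[positive, markers] <- theta[positive, markers] +
      rep(signs * cfg$effect_size, each = sum(positive))
  list(mu = mu, theta = theta)
}

.truncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# Missingness biased toward low intensities: inclusion weight decays with
# the standardised log intensity (censoring-like, missing-not-at-random).
.inject_missing <- function(m, rate) {
  if (rate <= 0) return(m)
  lv <- log(m)
  z <- (lv - mean(lv)) / stats::sd(lv)
  w <- exp(-2 * z)
  n_miss <- round(rate * length(m))
  if (n_miss == 0) return(m)
  orig <- m
  idx <- sample.int(length(m), n_miss, prob = w)
  m[idx] <- NA_real_
  # keep at least one observed positive value per feature
  for (j in seq_len(ncol(m)))
    if (all(is.na(m[, j]))) {
      i <- sample.int(nrow(m), 1L)
      m[i, j] <- orig[i, j]
    }
  m
}

#' Generate a synthetic two-platform cohort
#'
#' Produces a fecal-headspace table (biological samples plus microchamber and
#' instrument blanks, with duplicates, per-sample dilution factors and
#' censoring-like missingness), a breath table (one curated sample per
#' patient), and a truth record of the planted structure. Intensities are
#' log-normal; duplicates of a patient share the biological signal and differ
#' only by measurement noise and dilution; blood markers are generated from
#' the latent breath-marker signal so that they are elevated in the positive
#' class and correlated with the designated breath markers.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `fecal` ([VOCExperiment-class]), `breath`
#'   ([VOCExperiment-class]) and `truth` (planted markers, signs, blank-leak
#'   features, patient groups).
#' @export
generateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    groups <- rep(.GROUPS, c(cfg$n_psc, cfg$n_psc_ibd, cfg$n_ibd))
    n_pat <- length(groups)
    if (n_pat == 0L) stop("cohort has no patients")
    patients <- sprintf("P%03d", seq_len(n_pat))
    positive <- groups != "IBD"

    ## ---- fecal platform ----
    pf <- cfg$n_features_fecal
    feat_f <- .feature_names("fecal", pf)
    mk_f <- sort(sample.int(pf, cfg$n_markers))
    sg_f <- rep_len(c(1, -1), cfg$n_markers)
    sig_f <- .patient_signal(pf, positive, mk_f, sg_f, cfg)

    n_dup <- 1L + (stats::runif(n_pat) < cfg$duplicate_rate)
    rows <- rep(seq_len(n_pat), n_dup)
    dup_idx <- unlist(lapply(n_dup, seq_len))
    n_samp <- length(rows)
    dil <- stats::rnorm(n_samp, 0, cfg$dilution_sd)
    logv <- sig_f$theta[rows, , drop = FALSE] +
      matrix(stats::rnorm(n_samp * pf, 0, cfg$meas_sd), nrow = n_samp) + dil
    vals_f <- .inject_missing(exp(logv), cfg$missing_rate)
    colnames(vals_f) <- feat_f

    water <- .truncnorm(n_pat, cfg$water_mean_by_group[groups],
                        cfg$water_sd)

    ## ---- breath platform ----
    pb <- cfg$n_features_breath
    feat_b <- .feature_names("breath", pb)
    mk_b <- sort(sample.int(pb, cfg$n_markers))
    sg_b <- rep_len(1, cfg$n_markers)  # breath markers elevated in PSC
    sig_b <- .patient_signal(pb, positive, mk_b, sg_b, cfg)
    logb <- sig_b$theta +
      matrix(stats::rnorm(n_pat * pb, 0, cfg$meas_sd), nrow = n_pat)
    vals_b <- exp(logb)
    colnames(vals_b) <- feat_b

    ## ---- blood markers linked to breath markers ----
    blood_feats <- feat_b[mk_b[seq_len(min(4L, length(mk_b)))]]
    Lz <- if (length(blood_feats)) {
      L <- rowMeans(sig_b$theta[, mk_b[seq_len(min(4L, length(mk_b)))],
                                drop = FALSE])
      if (stats::sd(L) > 0) (L - mean(L)) / stats::sd(L) else L * 0
    } else stats::rnorm(n_pat)  # no planted markers: blood is pure noise
    rho <- cfg$blood_link_strength
    blood_mu <- c(ALP = 120, AST = 35, ALT = 40, bilirubin = 12)
    blood <- vapply(.BLOOD, function(b) {
      blood_mu[[b]] * exp(0.4 * (rho * Lz +
        sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_pat)))
    }, numeric(n_pat))

    severity <- ifelse(positive, stats::rnorm(n_pat, 2, 0.5), NA_real_)

    meta_f <- data.frame(
      sample_id = sprintf("%s_F%d", patients[rows], dup_idx),
      patient_id = patients[rows], group = groups[rows],
      role = "biological", duplicate_index = dup_idx,
      water_content = water[rows],
      ALP = blood[rows, "ALP"], AST = blood[rows, "AST"],
      ALT = blood[rows, "ALT"], bilirubin = blood[rows, "bilirubin"],
      severity_score = severity[rows], stringsAsFactors = FALSE)

    blanks <- generateBlanks(cfg, stats::setNames(sig_f$mu, feat_f),
                             seed = sample.int(2147483646L, 1L),
                             exclude = feat_f[mk_f])

    fecal <- VOCExperiment(rbind(vals_f, intensities(blanks$table)),
                           rbind(meta_f, sampleData(blanks$table)))

    meta_b <- data.frame(
      sample_id = sprintf("%s_B", patients),
      patient_id = patients, group = groups, role = "biological",
      duplicate_index = 1L, water_content = NA_real_,
      ALP = blood[, "ALP"], AST = blood[, "AST"], ALT = blood[, "ALT"],
      bilirubin = blood[, "bilirubin"], severity_score = severity,
      stringsAsFactors = FALSE)
    breath <- VOCExperiment(vals_b, meta_b)

    list(fecal = fecal, breath = breath,
         truth = list(
           fecal_markers = feat_f[mk_f], fecal_signs = sg_f,
           breath_markers = feat_b[mk_b], breath_signs = sg_b,
           blood_linked_breath = blood_feats,
           leak_features = blanks$leak_features,
           patient_groups = stats::setNames(groups, patients),
           positive_patients = patients[positive]))
  })
}

#' Generate microchamber and instrument blank samples
#'
#' Blank intensities sit far below the biological level for true headspace
#' features; for a `blank_leak` fraction of features the blanks are drawn at
#' (slightly above) the sample-comparable level, so the blank-retention rule
#' removes exactly those. Microchamber and instrument blank distributions
#' overlap.
#'
#' @param config a [simulationConfig()].
#' @param feature_log_means named numeric vector of per-feature baseline log
#'   intensities of the biological samples.
#' @param seed integer seed.
#' @param exclude feature names ineligible for the leak set (the cohort
#'   generator excludes planted markers, whose class shift would otherwise
#'   make the planted truth incoherent with the blank filter).
#' @return list with `table` (a [VOCExperiment-class] of blank samples) and
#'   `leak_features` (character).
#' @export
generateBlanks <- function(config, feature_log_means, seed = config$seed,
                           exclude = character()) {
  stopifnot(inherits(config, "SimulationConfig"))
  mu <- feature_log_means
  p <- length(mu)
  withr::with_seed(as.integer(seed), {
    n_leak <- round(config$blank_leak * p)
    eligible <- which(!names(mu) %in% exclude)
    n_leak <- min(n_leak, length(eligible))
    leak <- sort(sample(eligible, n_leak))
    lvl <- function(n, shift_clean, shift_leak, sd) {
      base <- matrix(rep(mu, each = n), nrow = n) + shift_clean
      if (n_leak)
        base[, leak] <- matrix(rep(mu[leak], each = n), nrow = n) + shift_leak
      exp(base + matrix(stats::rnorm(n * p, 0, sd), nrow = n))
    }
    n_mc <- config$n_mc_blanks
    n_in <- config$n_instrument_blanks
    vals <- rbind(
      if (n_mc) lvl(n_mc, -4, 0.5, 0.4),
      if (n_in) lvl(n_in, -4.2, 0.5, 0.4))
    roles <- rep(c("mc_blank", "instrument_blank"), c(n_mc, n_in))
    ids <- sprintf("BLK_%s_%d", ifelse(roles == "mc_blank", "MC", "IN"),
                   unlist(lapply(c(n_mc, n_in), seq_len)))
    if (length(roles) == 0L) {
      vals <- matrix(numeric(0), nrow = 0, ncol = p)
      ids <- character(0)
    }
    colnames(vals) <- names(mu)
    meta <- data.frame(sample_id = ids, patient_id = ids,
                       group = NA_character_, role = roles,
                       duplicate_index = 1L, stringsAsFactors = FALSE)
    list(table = VOCExperiment(vals, meta),
         leak_features = names(mu)[leak])
  })
}
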