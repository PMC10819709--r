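test_that("duplicate pairs never straddle a train/test boundary", {
  co <- generateCohort(small_sim(20))
  lab <- mergePscGroups(co$fecal)
  info <- data.frame(sample_id = lab@sampleIds, patient_id = lab@patientIds,
                     label = as.character(lab@labels))
  cfg <- selectionConfig(seed = 1)
  for (s in 1:100) {
    sp <- splitDuplicateSafe(info, cfg, seed = s)
    side <- ifelse(info$sample_id %in% sp$train, "train", "test")
    expect_true(all(tapply(side, info$patient_id,
                           function(v) length(unique(v))) == 1L))
  }
  # class-wise patient counts near the configured fractions
  sp <- splitDuplicateSafe(info, cfg, seed = 7)
  tr_pat <- unique(info$patient_id[info$sample_id %in% sp$train])
  pat_lab <- tapply(info$label, info$patient_id, `[`, 1L)
  expect_equal(sum(pat_lab[tr_pat] == "PSC"), round(0.83 * 10),
               tolerance = 1)
  expect_equal(sum(pat_lab[tr_pat] == "IBD"), round(0.73 * 14),
               tolerance = 1)
  # singletons reduce to an ordinary stratified split
  singles <- info[!duplicated(info$patient_id), ]
  sp2 <- splitDuplicateSafe(singles, cfg, seed = 3)
  expect_length(intersect(sp2$train, sp2$test), 0L)
  expect_setequal(c(sp2$train, sp2$test), singles$sample_id)
})

test_that("ROC metrics match exhaustive pair counting", {
  labs <- factor(c("PSC", "PSC", "IBD", "PSC", "IBD", "IBD"),
                 levels = c("IBD", "PSC"))
  probs <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  r <- rocMetrics(probs, labs)
  expect_equal(r$auc, oracle_auc_pairs(probs, labs))
  # perfect and uninformative scores
  perf <- rocMetrics(c(1, 1, 0, 1, 0, 0), labs)
  expect_equal(c(perf$auc, perf$sensitivity, perf$specificity), c(1, 1, 1))
  expect_equal(rocMetrics(rep(0.5, 6), labs)$auc, 0.5)
  expect_error(rocMetrics(probs[1:2], factor(c("PSC", "PSC"),
                                             levels = c("IBD", "PSC"))),
               "both classes")
  # random score vectors against the oracle
  for (s in 1:20) {
    withr::with_seed(s, {
      pr <- runif(20)
      ll <- factor(sample(c("IBD", "PSC"), 20, replace = TRUE,
                          prob = c(0.6, 0.4)), levels = c("IBD", "PSC"))
    })
    if (nlevels(droplevels(ll)) < 2) next
    expect_equal(rocMetrics(pr, ll)$auc, oracle_auc_pairs(pr, ll))
  }
})

test_that("a perfectly separating feature yields AUC 1", {
  n <- 24
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     patient_id = sprintf("p%d", 1:n),
                     group = rep(c("PSC", "IBD"), each = n / 2),
                     role = "biological")
  withr::with_seed(1, {
    vals <- cbind(sep = c(runif(n / 2, 10, 12), runif(n / 2, 1, 3)),
                  noise = rlnorm(n))
  })
  x <- VOCExperiment(vals, meta)
  res <- suppressWarnings(
    fitEvaluate(x, NULL, "sep",
                selectionConfig(n_iterations = 25, rf_trees = 100, seed = 2)))
  expect_equal(modelAUC(res), 1)
  expect_true(validObject(proximity(res)))
  expect_equal(dim(res@pcoa), c(n, 2L))
})

test_that("fitted models on planted cohorts separate held-out samples", {
  co <- generateCohort(small_sim(21, effect_size = 1.2))
  mk <- co$truth$fecal_markers
  other <- setdiff(rownames(co$fecal), mk)[1:3]
  pairs <- expand.grid(num = mk, den = other, stringsAsFactors = FALSE)
  res <- fitEvaluate(subsetByRole(co$fecal), NULL, pairs,
                     selectionConfig(n_iterations = 40, rf_trees = 150,
                                     seed = 3))
  expect_gt(modelAUC(res), 0.9)
  expect_true(all(probabilities(res) >= 0 & probabilities(res) <= 1,
                  na.rm = TRUE))
  expect_error(fitEvaluate(subsetByRole(co$fecal), NULL,
                           data.frame(num = "absent", den = mk[1]),
                           selectionConfig(seed = 1)), "unknown feature")
})

test_that("the water-content-only model behaves as a bias check", {
  co <- generateCohort(small_sim(22))
  cfg <- selectionConfig(n_iterations = 25, rf_trees = 100, seed = 4)
  wm <- suppressWarnings(waterContentModel(subsetByRole(co$fecal), NULL, cfg))
  expect_true(is.finite(modelAUC(wm)))
  expect_true(all(c("water_deviation", "probability") %in%
                    colnames(wm@extra$water_scatter)))
  # perfectly separating water content
  x <- subsetByRole(co$fecal)
  sd_ <- sampleData(x)
  sep <- ifelse(sd_$group == "IBD", 60, 90) + seq_len(nrow(sd_)) * 1e-3
  cd <- SummarizedExperiment::colData(x)
  cd$water_content <- sep
  SummarizedExperiment::colData(x) <- cd
  wm2 <- suppressWarnings(waterContentModel(x, NULL, cfg))
  expect_equal(modelAUC(wm2), 1)
  # degenerate inputs
  cd$water_content <- 75
  SummarizedExperiment::colData(x) <- cd
  expect_error(waterContentModel(x, NULL, cfg), "no variation")
  cd$water_content[3] <- NA
  SummarizedExperiment::colData(x) <- cd
  expect_error(waterContentModel(x, NULL, cfg), sd_$sample_id[3])
})

test_that("proximity pseudo-F flags structure and respects its p floor", {
  # two proximity blocks defined by the covariate
  n <- 30
  blocks <- rep(c(0, 1), each = n / 2)
  P <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.9, 0.1))
  diag(P) <- 1
  prox <- new("ProximityMatrix", values = P,
              sampleIds = sprintf("s%d", 1:n))
  res <- proximityCovariateTest(prox, blocks + rnorm(n, 0, 0.01),
                                n_perm = 199, seed = 2)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 200)       # attainable floor
  expect_error(proximityCovariateTest(prox, blocks, n_perm = 50), "99")
  expect_error(proximityCovariateTest(prox, blocks[-1], n_perm = 99),
               "length")
})

test_that("null covariates give approximately uniform pseudo-F p-values", {
  co <- generateCohort(small_sim(23))
  res <- suppressWarnings(
    fitEvaluate(subsetByRole(co$fecal), NULL,
                data.frame(num = rownames(co$fecal)[1],
                           den = rownames(co$fecal)[2]),
                selectionConfig(n_iterations = 10, rf_trees = 80,
                                seed = 5)))
  prox <- proximity(res)
  ps <- vapply(1:60, function(s) {
    cov <- withr::with_seed(1000 + s, rnorm(length(sampleIds(prox))))
    proximityCovariateTest(prox, cov, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("severity strata partition positives and preserve null AUC", {
  co <- generateCohort(small_sim(24, effect_size = 1.2))
  mk <- co$truth$fecal_markers
  res <- fitEvaluate(subsetByRole(co$fecal), NULL,
                     expand.grid(num = mk,
                                 den = setdiff(rownames(co$fecal), mk)[1:2],
                                 stringsAsFactors = FALSE),
                     selectionConfig(n_iterations = 30, rf_trees = 100,
                                     seed = 6))
  labs <- res@labels
  pos_ids <- names(labs)[labs == "PSC"]
  withr::with_seed(9, sev <- setNames(rnorm(length(pos_ids), 2, 0.5),
                                      pos_ids))
  fr <- list(c(0, 0.5), c(0.5, 1))
  # the bands are disjoint and exhaustive on the positive samples
  rk <- rank(sev, ties.method = "first") / length(sev)
  band1 <- names(sev)[rk > 0 & rk <= 0.5]
  band2 <- names(sev)[rk > 0.5 & rk <= 1]
  expect_length(intersect(band1, band2), 0L)
  expect_setequal(c(band1, band2), pos_ids)
  sa <- stratifiedAuc(res, sev, fr)
  # severity unrelated to the scores: stratum AUCs track the overall AUC
  expect_true(all(abs(sa - modelAUC(res)) < 0.15))
  # a single positive in a stratum still yields a defined AUC
  one <- stratifiedAuc(res, sev, list(c(0, 1 / length(sev))))
  expect_true(is.finite(one))
  expect_error(stratifiedAuc(res, sev, list(c(0.999, 0.9999))), "empty")
})
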