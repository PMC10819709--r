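# Minimal patient-level ModelResult carrying just what fusion needs.
mock_result <- function(P, ids, labels, patient_ids = ids) {
  new("ModelResult",
      probabilities = setNames(rep(0.5, length(ids)), ids),
      labels = factor(labels, levels = c("IBD", "PSC")),
      sampleInfo = data.frame(sample_id = ids, patient_id = patient_ids,
                              label = labels, stringsAsFactors = FALSE),
      selected = list(), proximity = .vocfusion_prox(P, ids),
      auc = 0.5, sensitivity = 0.5, specificity = 0.5, threshold = 0.5,
      rocCurve = data.frame(), pcoa = matrix(0, length(ids), 2),
      extra = list())
}

.vocfusion_prox <- function(P, ids) {
  dimnames(P) <- list(ids, ids)
  new("ProximityMatrix", values = P, sampleIds = ids)
}

rand_prox <- function(n, seed) {
  withr::with_seed(seed, {
    z <- matrix(runif(n * n), n)
    P <- (z + t(z)) / 2
  })
  diag(P) <- 1
  P
}

test_that("proximity stacking is the exact weighted elementwise average", {
  ids <- sprintf("p%d", 1:3)
  A <- .vocfusion_prox(matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3), ids)
  B <- .vocfusion_prox(matrix(c(1, .8, .0, .8, 1, .2, .0, .2, 1), 3), ids)
  expect_identical(proximity(stackProximities(A, B, 1)), proximity(A))
  expect_identical(proximity(stackProximities(A, B, 0)), proximity(B))
  expect_equal(proximity(stackProximities(A, B, 0.5)),
               (proximity(A) + proximity(B)) / 2)
  # affine in w
  w <- 0.3
  expect_equal(proximity(stackProximities(A, B, w)),
               w * proximity(A) + (1 - w) * proximity(B))
  expect_error(stackProximities(A, B, 1.2), "\\[0, 1\\]")
  for (w in seq(0, 1, 0.25))
    expect_true(validObject(stackProximities(A, B, w)))
})

test_that("alignment intersects patients and collapses fecal duplicates", {
  # fecal: 3 patients, first with two duplicates
  fids <- c("p1_a", "p1_b", "p2_a", "p3_a")
  fP <- rand_prox(4, 1)
  f <- mock_result(fP, fids, c("PSC", "PSC", "IBD", "IBD"),
                   patient_ids = c("p1", "p1", "p2", "p3"))
  # breath: patients p1, p2, p4
  bP <- rand_prox(3, 2)
  b <- mock_result(bP, c("p1", "p2", "p4"), c("PSC", "IBD", "IBD"))
  al <- alignSamples(f, b)
  expect_setequal(al$patients, c("p1", "p2"))
  # p1's fused row against p2 is the mean of its two duplicate rows
  expect_equal(proximity(al$P_fecal)["p1", "p2"],
               mean(fP[1:2, 3]))
  expect_equal(as.character(al$labels[c("p1", "p2")]), c("PSC", "IBD"))
  # identical patient sets: full-length index
  b2 <- mock_result(rand_prox(3, 3), c("p1", "p2", "p3"),
                    c("PSC", "IBD", "IBD"))
  expect_length(alignSamples(f, b2)$patients, 3L)
  # empty intersection
  b3 <- mock_result(rand_prox(2, 4), c("q1", "q2"), c("PSC", "IBD"))
  expect_error(alignSamples(f, b3), "no patients shared")
})

test_that("identical platforms make the fused AUC independent of w", {
  co <- generateCohort(small_sim(30, n_features_fecal = 8))
  mk <- co$truth$fecal_markers
  res <- fitEvaluate(subsetByRole(co$fecal), NULL,
                     expand.grid(num = mk[1:2],
                                 den = setdiff(rownames(co$fecal), mk)[1:2],
                                 stringsAsFactors = FALSE),
                     selectionConfig(n_iterations = 15, rf_trees = 100,
                                     seed = 2))
  al <- alignSamples(res, res)
  fus <- suppressWarnings(optimizeWeight(
    al$P_fecal, al$P_breath, al$labels,
    fusionConfig(weight_grid = c(0, 0.5, 1), n_iterations = 12,
                 rf_trees = 100, seed = 3)))
  expect_equal(diff(range(fus$auc_table$auc)), 0, tolerance = 1e-12)
  expect_equal(fus$w, 0.5)  # tie broken toward the agnostic mix
})

test_that("fusing complementary weak platforms preserves the better one", {
  gains <- numeric(3)
  for (r in 1:3) {
    cfg <- small_sim(40 + r, n_features_fecal = 12, n_features_breath = 10,
                     effect_size = 0.6)
    co <- generateCohort(cfg)
    mcfg <- selectionConfig(n_iterations = 25, rf_trees = 120, seed = r)
    mk <- co$truth$fecal_markers
    fpairs <- expand.grid(num = mk,
                          den = setdiff(rownames(co$fecal), mk)[1:3],
                          stringsAsFactors = FALSE)
    fm <- suppressWarnings(
      fitEvaluate(subsetByRole(co$fecal), NULL, fpairs, mcfg))
    bm <- suppressWarnings(
      fitEvaluate(co$breath, NULL, co$truth$breath_markers, mcfg))
    al <- alignSamples(fm, bm)
    fus <- suppressWarnings(optimizeWeight(
      al$P_fecal, al$P_breath, al$labels,
      fusionConfig(weight_grid = seq(0, 1, 0.1), n_iterations = 20,
                   rf_trees = 120, seed = r)))
    singles <- fus$auc_table$auc[fus$auc_table$w %in% c(0, 1)]
    gains[r] <- modelAUC(fus$result) - max(singles)
  }
  expect_true(mean(gains) >= -0.02)
})

test_that("the optimiser avoids a pure-noise platform", {
  cfg <- small_sim(51, n_features_fecal = 12, n_features_breath = 10,
                   n_markers = 3)
  co <- generateCohort(cfg)
  mcfg <- selectionConfig(n_iterations = 25, rf_trees = 120, seed = 3)
  mk <- co$truth$fecal_markers
  fm <- suppressWarnings(fitEvaluate(
    subsetByRole(co$fecal), NULL,
    expand.grid(num = mk, den = setdiff(rownames(co$fecal), mk)[1:3],
                stringsAsFactors = FALSE), mcfg))
  # a breath table with no planted signal, same patients
  noise <- generateCohort(small_sim(52, n_features_fecal = 12,
                                    n_features_breath = 10, n_markers = 0,
                                    effect_size = 0))
  bm <- suppressWarnings(fitEvaluate(noise$breath, mergePscGroups(co$breath),
                                     compounds(noise$breath), mcfg))
  al <- alignSamples(fm, bm)
  fus <- suppressWarnings(optimizeWeight(
    al$P_fecal, al$P_breath, al$labels,
    fusionConfig(weight_grid = seq(0, 1, 0.1), n_iterations = 25,
                 rf_trees = 120, seed = 4)))
  expect_gte(fus$w, 0.5)                       # informative (fecal) end
  auc0 <- fus$auc_table$auc[fus$auc_table$w == 0]
  expect_gt(modelAUC(fus$result), auc0 + 0.15)
})

test_that("degenerate fused matrices are rejected", {
  ids <- sprintf("p%d", 1:6)
  allone <- .vocfusion_prox(matrix(1, 6, 6), ids)
  labs <- factor(rep(c("IBD", "PSC"), 3), levels = c("IBD", "PSC"))
  expect_error(fitFused(allone, labs, fusionConfig(seed = 1)), "rank 0")
  # a single-value grid is returned as-is
  co_grid <- fusionConfig(weight_grid = 0.3, n_iterations = 5,
                          rf_trees = 50, seed = 2)
  P <- .vocfusion_prox(rand_prox(6, 5), ids)
  Q <- .vocfusion_prox(rand_prox(6, 6), ids)
  fus <- suppressWarnings(optimizeWeight(P, Q, labs, co_grid))
  expect_equal(fus$w, 0.3)
  expect_equal(nrow(fus$auc_table), 1L)
})
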