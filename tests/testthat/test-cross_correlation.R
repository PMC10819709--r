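test_that("the first canonical variate reduces to Pearson in one dimension", {
  withr::with_seed(1, {
    x <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "x"))
    y <- 2 * x + matrix(rnorm(40, 0, 0.3), ncol = 1,
                        dimnames = list(NULL, "y"))
  })
  cc <- ccaFirstVariate(x, y, n_permutations = 99, seed = 2)
  expect_equal(cc$r1, abs(cor(x, y)[1, 1]), tolerance = 1e-6)
  expect_lte(cc$p_value, 0.05)
  # identical single columns correlate perfectly
  cc2 <- ccaFirstVariate(x, x, n_permutations = 49, seed = 3)
  expect_equal(cc2$r1, 1, tolerance = 1e-9)
  # rank deficiency falls back to a ridge-regularised fit with a warning
  xx <- cbind(x, x)
  colnames(xx) <- c("a", "b")
  expect_warning(ccaFirstVariate(xx, y, n_permutations = 49, seed = 4),
                 "ridge")
})

test_that("permutation p-values are approximately uniform under the null", {
  ps <- vapply(1:40, function(s) {
    withr::with_seed(2000 + s, {
      X <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, paste0("x", 1:3)))
      Y <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, paste0("y", 1:3)))
    })
    ccaFirstVariate(X, Y, n_permutations = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("recursive elimination stops at significance or the floor", {
  withr::with_seed(5, {
    z <- rnorm(50)
    X <- cbind(x_link = z + 0.3 * rnorm(50), matrix(rnorm(50 * 3), 50))
    colnames(X)[2:4] <- paste0("x_n", 1:3)
    Y <- cbind(y_link = z + 0.3 * rnorm(50), matrix(rnorm(50 * 3), 50))
    colnames(Y)[2:4] <- paste0("y_n", 1:3)
  })
  cfg <- correlationConfig(n_iterations = 10, n_permutations = 99, seed = 6)
  # an already-significant pair needs no elimination
  pre <- rfeToSignificance(X[, "x_link", drop = FALSE],
                           Y[, "y_link", drop = FALSE], cfg)
  expect_true(pre$significant)
  expect_equal(pre$n_dropped, 0L)
  # the planted pair survives elimination from noise
  hits <- 0
  for (r in 1:10) {
    sel <- rfeToSignificance(X, Y, cfg, seed = r)
    hits <- hits + (sel$significant && "x_link" %in% sel$selected_x &&
                      "y_link" %in% sel$selected_y)
  }
  expect_gte(hits, 8)
  # all-noise input ends flagged non-significant at the two-feature floor
  withr::with_seed(7, {
    Xn <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("x", 1:4)))
    Yn <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("y", 1:4)))
  })
  noise <- rfeToSignificance(Xn, Yn,
                             correlationConfig(n_iterations = 10,
                                               n_permutations = 199,
                                               alpha = 0.01, seed = 8))
  if (!noise$significant) {
    expect_length(noise$selected_x, 2L)
    expect_length(noise$selected_y, 2L)
  }
})

test_that("the permutation screen separates linked from permuted features", {
  withr::with_seed(9, {
    z <- rnorm(60)
    X <- cbind(x_link = exp(9 + z + 0.4 * rnorm(60)),
               matrix(exp(rnorm(60 * 2, 9, 1)), 60))
    colnames(X)[2:3] <- paste0("x_n", 1:2)
    X[sample(length(X), 25)] <- NA
    Y <- cbind(y_link = z + 0.4 * rnorm(60), matrix(rnorm(60 * 2), 60))
    colnames(Y)[2:3] <- paste0("y_n", 1:2)
  })
  Xs <- function(seed) log(imputeMissing(X, seed))
  cfg <- correlationConfig(n_iterations = 25, n_permutations = 49, seed = 10)
  scr <- permutationScreen(Xs, Y, cfg)
  expect_true("x_link" %in% scr$selected_x)
  expect_true("y_link" %in% scr$selected_y)
  expect_true(all(c("real", "permuted", "p") %in% colnames(scr$counts)))
  expect_error(permutationScreen(Xs, Y,
                                 correlationConfig(n_iterations = 1,
                                                   seed = 1)),
               "insufficient iterations")
})

test_that("Fisher-z averaging matches its closed forms", {
  expect_equal(fisherZMean(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisherZMean(c(0, 0.8)), tanh(atanh(0.8) / 2),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fisherZMean(c(0, 0.8)), 0.4)))
  # order-invariant, identity on constants
  withr::with_seed(11, r <- runif(9, -0.9, 0.9))
  expect_equal(fisherZMean(r), fisherZMean(rev(r)))
  expect_equal(fisherZMean(rep(0.73, 5)), 0.73, tolerance = 1e-12)
})

test_that("averaging over imputations is idempotent without missingness", {
  withr::with_seed(12, {
    z <- rnorm(40)
    X <- matrix(c(z + 0.2 * rnorm(40), rnorm(40)), 40,
                dimnames = list(NULL, c("x1", "x2")))
    Y <- matrix(c(z + 0.2 * rnorm(40), rnorm(40)), 40,
                dimnames = list(NULL, c("y1", "y2")))
  })
  cfg <- correlationConfig(n_iterations = 5, n_permutations = 99, seed = 13)
  res <- averagedCorrelations(X, Y, colnames(X), colnames(Y), cfg)
  one <- ccaFirstVariate(X, Y, n_permutations = 99, seed = 1)
  expect_equal(res@canonicalR, one$r1, tolerance = 1e-9)
  expect_true(res@significant)
  expect_equal(nrow(res@univariate), 4L)
  expect_true(all(res@univariate$p_adj >= res@univariate$p - 1e-12))
  expect_error(averagedCorrelations(X, Y, character(0), colnames(Y), cfg),
               "non-empty")
})

test_that("blood association recovers the planted breath-blood link", {
  co <- generateCohort(simulationConfig(seed = 41))
  sd_ <- sampleData(co$breath)
  pos <- sd_$group != "IBD"
  br <- log(intensities(co$breath)[pos, , drop = FALSE])
  bl <- as.matrix(sd_[pos, c("ALP", "AST", "ALT", "bilirubin")])
  cfg <- correlationConfig(n_iterations = 15, n_permutations = 99, seed = 5)
  res <- suppressWarnings(bloodAssociation(br, bl, cfg))
  expect_gte(res@canonicalR, 0.8)
  # shuffled blood rows: no meaningful association
  withr::with_seed(6, blp <- bl[sample(nrow(bl)), ])
  null <- suppressWarnings(bloodAssociation(br, blp, cfg))
  expect_false(null@significant)
  # degenerate inputs
  expect_error(bloodAssociation(br[1:4, ], bl[1:4, ], cfg), "fewer than 6")
  blc <- bl; blc[, "bilirubin"] <- 7
  w <- capture_warnings(
    bloodAssociation(br, blc, correlationConfig(n_iterations = 4,
                                                n_permutations = 49,
                                                seed = 7)))
  expect_true(any(grepl("constant blood column", w)))
})
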