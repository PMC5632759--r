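test_that("identical within-block features give BP = 1 at every scale", {
  ## two blocks, orthogonal patterns, members identical within a block
  f1 <- c(rep(10, 5), rep(0, 5)) + seq(0.1, 1, by = 0.1)
  f2 <- c(rep(0, 5), rep(10, 5)) + seq(1, 0.1, by = -0.1)
  fm <- cbind(a1 = f1, a2 = f1, b1 = f2, b2 = f2)
  for (r in c(0.6, 1, 1.3)) {
    bp <- bootstrapBP(fm, nBoot = 200, scale = r, seed = 3)
    blocks <- bp$bp[bp$members %in% c("a1+a2", "b1+b2")]
    expect_equal(blocks, c(1, 1))
  }
  ## only internal edges are scored: n - 1 rows, every member set >= 2
  bp <- bootstrapBP(fm, nBoot = 200, scale = 1, seed = 3)
  expect_equal(nrow(bp), 3L)
  expect_true(all(lengths(strsplit(bp$members, "+", fixed = TRUE)) >= 2))
})

test_that("bootstrap configuration is validated", {
  fm <- simulateFeatureMatrix(4, 8, seed = 1)
  expect_error(msBootstrap(fm, nBoot = 0), "at least 100")
  expect_error(bootstrapBP(fm, nBoot = 0), "at least 100")
  expect_error(bootstrapBP(fm, nBoot = 200, scale = 0.1), "sample sizes < 2")
  expect_error(msBootstrap(fm, nBoot = 200, scales = c(0.5, 0.8)),
               "include 1.0")
  expect_error(msBootstrap(fm[1:3, ], nBoot = 200), "at least 4 feature")
  expect_error(msBootstrap(fm[, 1:2], nBoot = 200), "at least 3 complexes")
})

test_that("the probit fit reproduces its algebraic special cases", {
  scales <- seq(0.5, 1.4, by = 0.1)
  ## BP = 0.5 everywhere: v = c = 0, AU = 0.5
  fit <- multiscaleAU(matrix(500L, 1, 10), 1000, scales)
  expect_equal(fit$v, 0, tolerance = 1e-9)
  expect_equal(fit$c, 0, tolerance = 1e-9)
  expect_equal(fit$au, 0.5, tolerance = 1e-9)

  ## counts generated from z = v*sqrt(r) exactly (c = 0):
  ## AU equals the model-implied BP at r = 1
  v <- 0.7
  cnt <- matrix(round(1e6 * pnorm(v * sqrt(scales), lower.tail = FALSE)), 1)
  fit <- multiscaleAU(cnt, 1e6, scales)
  expect_equal(fit$c, 0, tolerance = 5e-3)
  expect_equal(fit$au, fit$bp.model, tolerance = 1e-3)
  expect_equal(fit$au, pnorm(v, lower.tail = FALSE), tolerance = 2e-3)

  ## degenerate edges: all-extreme counts fall back to BP with SE 0
  fit <- multiscaleAU(matrix(1000L, 1, 10), 1000, scales)
  expect_true(fit$degenerate)
  expect_equal(fit$au, 1); expect_equal(fit$se.au, 0)
  fit0 <- multiscaleAU(matrix(0L, 1, 10), 1000, scales)
  expect_equal(fit0$au, 0); expect_equal(fit0$se.au, 0)
  ## too few scales to fit: flagged, SE NaN
  fit2 <- multiscaleAU(matrix(c(500L, 700L), 1, 2), 1000, c(0.5, 1))
  expect_true(fit2$degenerate)
  expect_true(is.nan(fit2$se.au))
  expect_equal(fit2$au, 0.7)
})

test_that("the WLS fit matches an independent lm-based implementation", {
  set.seed(6)
  scales <- seq(0.5, 1.4, by = 0.1)
  cnt <- matrix(as.integer(round(1000 * runif(10, 0.15, 0.85))), 1)
  fit <- multiscaleAU(cnt, 1000, scales)
  bp <- cnt[1, ] / 1000
  z <- qnorm(1 - bp)
  w <- dnorm(z)^2 * 1000 / (bp * (1 - bp))
  lmfit <- lm(z ~ 0 + I(sqrt(scales)) + I(1 / sqrt(scales)), weights = w)
  cf <- unname(coef(lmfit))
  ## covariance with known (not residual-estimated) variances
  cov <- summary(lmfit)$cov.unscaled
  expect_equal(fit$v, cf[1], tolerance = 1e-9)
  expect_equal(fit$c, cf[2], tolerance = 1e-9)
  expect_equal(fit$au, 1 - pnorm(cf[1] - cf[2]), tolerance = 1e-9)
  expect_equal(fit$se.au,
               dnorm(cf[1] - cf[2]) *
                 sqrt(cov[1, 1] + cov[2, 2] - 2 * cov[1, 2]),
               tolerance = 1e-9)
})

test_that("bootstrap results are a pure function of seed and config", {
  fm <- simulateFeatureMatrix(8, 16, contrast = 4, noise = 1, seed = 9)
  d1 <- msBootstrap(fm, nBoot = 300, seed = 17)
  d2 <- msBootstrap(fm, nBoot = 300, seed = 17)
  expect_identical(edgeSupport(d1), edgeSupport(d2))
  expect_identical(toNewick(d1), toNewick(d2))
  d3 <- msBootstrap(fm, nBoot = 300, seed = 18)
  expect_false(identical(edgeSupport(d1)$bp, edgeSupport(d3)$bp))
})

test_that("the replicate engine's tree matches the R UPGMA implementation", {
  set.seed(30)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    fm <- matrix(rnorm(n * 20), 20, n,
                 dimnames = list(NULL, paste0("c", seq_len(n))))
    hc <- upgma(correlationDistance(fm))
    masks <- pMHCsurf:::upgma_masks_cpp(as.matrix(correlationDistance(fm)))
    cppSets <- apply(masks, 1, function(r) paste(which(r == 1), collapse = ","))
    rSets <- vapply(pMHCsurf:::.edgeMembers(hc), paste, character(1),
                    collapse = ",")
    expect_equal(sort(cppSets), sort(rSets))
  }
})

test_that("support values stay in [0,1] with finite SEs on fitted edges", {
  fm <- simulateFeatureMatrix(10, 20, rep(1:2, each = 5), contrast = 3,
                              noise = 1.5, seed = 23)
  dend <- msBootstrap(fm, nBoot = 500, seed = 23)
  e <- edgeSupport(dend)
  expect_true(all(e$au >= 0 & e$au <= 1))
  expect_true(all(e$bp >= 0 & e$bp <= 1))
  expect_true(all(is.finite(e$se.au[!e$degenerate])))
  expect_true(all(e$df[!e$degenerate] >= 1))
})

test_that("planted partitions are recovered at the midpoint cut", {
  ## noise well below the planted contrast: ARI = 1 in >= 95/100 seeded runs
  hits <- 0L
  for (seed in 1:100) {
    fm <- simulateFeatureMatrix(12, 30, contrast = 10, noise = 1, seed = seed)
    hc <- upgma(correlationDistance(fm))
    thr <- mean(sort(hc$height, decreasing = TRUE)[1:2])
    part <- cutDendrogram(hc, thr)
    hits <- hits + as.integer(
      mclust::adjustedRandIndex(part, attr(fm, "partition")) == 1)
  }
  expect_gte(hits, 95L)
})

test_that("median true-edge AU does not decrease with planted contrast", {
  medAU <- vapply(c(2, 5, 10), function(contrast) {
    aus <- c()
    for (seed in 1:5) {
      fm <- simulateFeatureMatrix(12, 30, contrast = contrast, noise = 1,
                                  seed = seed)
      dend <- msBootstrap(fm, nBoot = 500, seed = seed)
      e <- edgeSupport(dend)
      true <- c(paste(colnames(fm)[1:6], collapse = "+"),
                paste(colnames(fm)[7:12], collapse = "+"))
      aus <- c(aus, e$au[e$members %in% true])
    }
    median(aus)
  }, numeric(1))
  expect_true(all(diff(medAU) >= 0))
})
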