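test_that("focal loss matches hand-computed values and a BCE oracle", {
  # single pixel, truth 1, prediction 0.5: (1 - 0.5)^4 * ln 2
  expect_equal(focalLoss(matrix(0.5), matrix(1)), 0.5^4 * log(2),
               tolerance = 1e-9)
  # perfect prediction
  eps <- 1e-7
  expect_lt(focalLoss(matrix(1 - eps, 4, 4), matrix(1, 4, 4)), 1e-6)
  # gamma = 0 reduces to mean binary cross-entropy (independent oracle)
  set.seed(1)
  p <- matrix(runif(64, 0.05, 0.95), 8)
  s <- matrix(rbinom(64, 1, 0.3), 8)
  bce <- -mean(s * log(p) + (1 - s) * log(1 - p))
  expect_equal(focalLoss(p, s, alpha = 1, gamma = 0), bce,
               tolerance = 1e-12)
  expect_error(focalLoss(matrix(0.5), matrix(1, 2, 2)), "mismatch")
})

test_that("focal loss is nonnegative and monotone in p_t", {
  ps <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(ps, function(p) focalLoss(matrix(p), matrix(1)),
                   numeric(1))
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))  # decreasing as p_t grows
  # analytic gradient agrees with finite differences
  g <- polypseg:::focalLossGrad(matrix(0.3), matrix(1))
  num <- (focalLoss(matrix(0.3 + 1e-6), matrix(1)) -
            focalLoss(matrix(0.3 - 1e-6), matrix(1))) / 2e-6
  expect_equal(as.numeric(g), num, tolerance = 1e-5)
  g0 <- polypseg:::focalLossGrad(matrix(0.7), matrix(0))
  num0 <- (focalLoss(matrix(0.7 + 1e-6), matrix(0)) -
             focalLoss(matrix(0.7 - 1e-6), matrix(0))) / 2e-6
  expect_equal(as.numeric(g0), num0, tolerance = 1e-5)
})

test_that("cosine schedule hits its endpoints and midpoint", {
  expect_equal(cosineLR(0, 5000), 0.01)
  expect_equal(cosineLR(5000, 5000), 0)
  expect_equal(cosineLR(2500, 5000), 0.005)
  expect_error(cosineLR(1, 0))
})

test_that("batch composition respects the synthetic fraction and seeds", {
  normals <- fixtureNormals(6)
  fakeSim <- function(seed) {
    img <- normals[[1]]
    m <- matrix(0, 64, 64); m[10:20, 10:20] <- 1
    new("SyntheticSample", image = img, mask = m, mode = "patch",
        alpha = NA_real_, seed = as.integer(seed))
  }
  b <- makeBatch(normals, fakeSim, batch = 8, syntheticFraction = 0.5,
                 targetSize = 64, seed = 1)
  expect_equal(sum(b$synthetic), 4L)
  expect_true(all(vapply(b$masks[!b$synthetic], sum, numeric(1)) == 0))
  expect_true(all(vapply(b$images, function(x)
    all(dim(x) == c(64, 64, 3)), logical(1))))
  b0 <- makeBatch(normals, fakeSim, batch = 4, syntheticFraction = 0,
                  targetSize = 64, seed = 2)
  expect_false(any(b0$synthetic))
  expect_true(all(vapply(b0$masks, sum, numeric(1)) == 0))
  b2 <- makeBatch(normals, fakeSim, batch = 8, syntheticFraction = 0.5,
                  targetSize = 64, seed = 1)
  expect_identical(b$normalIdx, b2$normalIdx)
  expect_error(makeBatch(list(), fakeSim), "no normal")
})

test_that("a short training run follows the schedule and selects by score", {
  normals <- fixtureNormals(12)
  tset <- fixtureTemplates()
  texs <- fixtureTextures(2)
  cfg <- trainConfig(inputSize = 64L, epochs = 3L, stepsPerEpoch = 1L,
                     batchSize = 4L, valPairs = 2L, evalEvery = 1L,
                     seed = 5L)
  ck <- trainModel(normals, tset, texs, cfg, smokeModelConfig(64L))
  expect_s4_class(ck, "SegCheckpoint")
  log <- ck@log
  expect_equal(nrow(log), 4L)  # epoch 0 (untrained) + 3 epochs
  # learning-rate trace matches the cosine schedule exactly
  expect_equal(log$lr[-1], cosineLR(0:2, 3))
  expect_true(all(is.finite(log$loss[-1])))
  # validation split is disjoint from the training set
  expect_length(intersect(attr(log, "trainNames"), attr(log, "valNames")),
                0)
  # retained checkpoint has the best selection score seen
  expect_equal(max(log$selScore, na.rm = TRUE),
               max(log$selScore[log$epoch == ck@epoch]))
  expect_equal(meanScore(ck), (ck@valIoU + ck@valDice) / 2)
  # same seeds reproduce the first-epoch loss
  ck2 <- trainModel(normals, tset, texs, cfg, smokeModelConfig(64L))
  expect_equal(ck2@log$loss[2], log$loss[2])
})

test_that("checkpoints round-trip through disk", {
  normals <- fixtureNormals(12)
  cfg <- trainConfig(inputSize = 64L, epochs = 1L, stepsPerEpoch = 1L,
                     batchSize = 2L, valPairs = 1L, seed = 6L)
  ck <- trainModel(normals, fixtureTemplates(), fixtureTextures(2), cfg,
                   smokeModelConfig(64L))
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(ck, f)
  r <- loadCheckpoint(f)
  img <- normals[[1]]
  expect_identical(predictProb(ck, img), predictProb(r, img))
})
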