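test_that("confusion counts match a per-pixel loop oracle", {
  a <- matrix(0, 10, 10); a[1:10, 1:10 <= 10] <- 0
  gt <- matrix(0, 10, 10); gt[1:10, 1:10] <- 1
  expect_equal(confusionCounts(gt, gt), c(tp = 100, fp = 0, fn = 0))
  p <- matrix(0, 10, 10); p[1, 1:10] <- 1
  g <- matrix(0, 10, 10); g[10, 1:10] <- 1
  expect_equal(confusionCounts(p, g), c(tp = 0, fp = 10, fn = 10))
  set.seed(7)
  pr <- matrix(rbinom(16, 1, 0.5), 4)
  gr <- matrix(rbinom(16, 1, 0.5), 4)
  tp <- fp <- fn <- 0
  for (i in 1:4) for (j in 1:4) {
    if (pr[i, j] == 1 && gr[i, j] == 1) tp <- tp + 1
    if (pr[i, j] == 1 && gr[i, j] == 0) fp <- fp + 1
    if (pr[i, j] == 0 && gr[i, j] == 1) fn <- fn + 1
  }
  expect_equal(confusionCounts(pr, gr), c(tp = tp, fp = fp, fn = fn))
  expect_error(confusionCounts(pr, matrix(0, 2, 2)), "mismatch")
})

test_that("overlap metrics follow their printed formulas", {
  m <- iouDice(c(tp = 50, fp = 25, fn = 25))
  expect_equal(unname(m["iou"]), 0.5)
  expect_equal(unname(m["dice"]), 2 / 3, tolerance = 1e-4)
  expect_equal(iouDice(c(tp = 7, fp = 0, fn = 0)), c(iou = 1, dice = 1))
  expect_equal(iouDice(c(tp = 0, fp = 3, fn = 2)), c(iou = 0, dice = 0))
  expect_equal(iouDice(c(tp = 0, fp = 0, fn = 0)), c(iou = 1, dice = 1))
  # algebraic identity Dice = 2 IoU / (1 + IoU) on random counts
  set.seed(11)
  for (i in 1:50) {
    cc <- c(tp = sample(0:200, 1), fp = sample(0:200, 1),
            fn = sample(0:200, 1))
    if (sum(cc) == 0) next
    m <- iouDice(cc)
    expect_equal(unname(m["dice"]),
                 unname(2 * m["iou"] / (1 + m["iou"])), tolerance = 1e-12)
  }
  # symmetric under swapping prediction and truth
  set.seed(12)
  pr <- matrix(rbinom(64, 1, 0.4), 8); gr <- matrix(rbinom(64, 1, 0.4), 8)
  expect_equal(iouDice(confusionCounts(pr, gr))["iou"],
               iouDice(confusionCounts(gr, pr))["iou"])
})

test_that("dataset evaluation aggregates per-image metrics", {
  pd <- withr::local_tempdir(); gd <- withr::local_tempdir()
  masks <- list(matrix(0, 8, 8), matrix(0, 8, 8), matrix(0, 8, 8))
  masks[[1]][2:5, 2:5] <- 1; masks[[2]][1:4, 1:8] <- 1
  masks[[3]][8, 8] <- 1
  for (i in 1:3) {
    writeMaskPNG(masks[[i]], file.path(pd, sprintf("m%d.png", i)))
    writeMaskPNG(masks[[i]], file.path(gd, sprintf("m%d.png", i)))
  }
  r <- evaluateDataset(pd, gd)
  expect_equal(r$meanIoU, 1); expect_equal(r$sdIoU, 0)
  expect_equal(r$meanDice, 1)
  # half-overlap case: mean of {1, 1/3} style values
  writeMaskPNG(matrix(0, 8, 8) + (row(matrix(0, 8, 8)) <= 2),
               file.path(pd, "m2.png"))
  r2 <- evaluateDataset(pd, gd)
  expect_equal(nrow(r2$perImage), 3L)
  expect_equal(r2$meanIoU, mean(r2$perImage$iou))
  popSd <- sqrt(mean((r2$perImage$iou - mean(r2$perImage$iou))^2))
  expect_equal(r2$sdIoU, popSd)
  ed <- withr::local_tempdir()
  expect_error(evaluateDataset(pd, ed), "matching")
})

test_that("sampling protocol behaves on degenerate and general scores", {
  r <- samplingEvaluation(rep(0.5, 600), trials = 20, seed = 1)
  expect_true(all(r$trialMeans == 0.5))
  expect_equal(r$sd, 0)
  set.seed(3)
  scores <- runif(700)
  r2 <- samplingEvaluation(scores, trials = 50, seed = 2)
  expect_true(all(r2$trialMeans >= min(scores) &
                    r2$trialMeans <= max(scores)))
  expect_error(samplingEvaluation(runif(100), trials = 5, seed = 1),
               "infeasible")
  # seeded replay oracle: independent re-implementation of the draw
  r3 <- samplingEvaluation(scores, trials = 5, seed = 9)
  replay <- withSeed(9, vapply(1:5, function(t) {
    idx <- sample.int(length(scores), 500)
    mean(colMeans(matrix(scores[idx], 100, 5)))
  }, numeric(1)))
  expect_equal(r3$trialMeans, replay)
})

test_that("trial-mean grand mean converges to the population mean", {
  set.seed(4)
  scores <- rbeta(900, 2, 3)
  r <- samplingEvaluation(scores, trials = 500, seed = 5)
  se <- r$sd / sqrt(500)
  expect_lt(abs(r$mean - mean(scores)), 2 * se + 1e-12)
})

test_that("paired t-test matches the hand formula and rejects degeneracy", {
  a <- c(0.5, 0.6, 0.7, 0.55, 0.65)
  b <- c(0.45, 0.5, 0.72, 0.5, 0.6)
  r <- pairedTTest(a, b)
  d <- a - b
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r$df, 4)
  # cross-check against the stock implementation
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_error(pairedTTest(a, a), "degenerate")
  expect_error(pairedTTest(a, a + 0.1), "degenerate")
  expect_error(pairedTTest(a, b[1:3]), "unequal")
})

test_that("bias patch is black, idempotent and local", {
  img <- generateMucosa(mucosaSpec(size = 96, seed = 13,
                                   thumbnail = "green"))
  p1 <- addBiasPatch(img)
  expect_true(all(p1[(96 - 63):96, 1:64, ] == 0))
  green <- p1[, , 1] == 0 & p1[, , 2] == 180 & p1[, , 3] == 0
  expect_equal(sum(green), 0)          # thumbnail fully covered
  expect_identical(addBiasPatch(p1), p1)
  outside <- img; outside[(96 - 63):96, 1:64, ] <- 0
  expect_identical(p1, outside)        # pixels outside the patch unchanged
  expect_error(addBiasPatch(array(0, dim = c(32, 32, 3))), "smaller")
})
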