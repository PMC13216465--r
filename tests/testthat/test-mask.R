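test_that("contour sampling follows the harmonic model", {
  set.seed(1)
  sp <- sampleContour(1000)
  expect_equal(sp$omega[1], 1)
  expect_equal(sp$omega[10], 0.01)     # quadratic amplitude decay
  expect_true(all(sp$phi >= 0 & sp$phi < 2 * pi))
  expect_true(all(sp$xi >= 0 & sp$xi <= 1))
  expect_error(sampleContour(0))
  # Monte-Carlo check that phases are uniform on [0, 2*pi)
  set.seed(2)
  phis <- replicate(10, sampleContour(1000)$phi)
  se <- (2 * pi / sqrt(12)) / sqrt(length(phis))
  expect_lt(abs(mean(phis) - pi), 3 * se)
})

test_that("radius evaluation matches the closed form and its bound", {
  set.seed(3)
  sp <- sampleContour(50)
  # zero perturbation -> unit circle
  sp0 <- sp; sp0$xi[] <- 0
  expect_equal(evaluateRadius(sp0, seq(0, 2 * pi, length.out = 17)),
               rep(1, 17))
  # single harmonic, direct evaluation
  sp1 <- sampleContour(1); sp1$xi[] <- 1; sp1$phi[] <- 0
  expect_equal(evaluateRadius(sp1, pi / 2), 2)
  # brute-force partial-sum bound
  theta <- seq(0, 2 * pi, length.out = 101)
  bound <- sum(sp$xi * sp$omega)
  expect_true(all(abs(evaluateRadius(sp, theta) - 1) <= bound + 1e-12))
  # 2*pi periodicity
  expect_lt(abs(evaluateRadius(sp, 0) - evaluateRadius(sp, 2 * pi)), 1e-9)
})

test_that("rasterization matches a point-in-disc oracle for the circle", {
  set.seed(4)
  sp <- sampleContour(100)
  sp$xi[] <- 0
  m <- rasterizeTemplate(sp, grid = 512)
  expect_length(attr(m, "bx"), 500)    # 50 points x density factor 10
  R <- 0.9 * 512 / 2
  ctr <- (512 + 1) / 2
  oracle <- sum(outer((1:512 - ctr)^2, (1:512 - ctr)^2, "+") <= R^2)
  expect_lt(abs(sum(m) - oracle) / oracle, 0.01)
})

test_that("rasterized templates are single 8-connected components", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- rasterizeTemplate(sampleContour(500), grid = 256)
    expect_equal(max(polypseg:::label8_cpp(m)), 1L)
  }
})

test_that("template sets are reproducible, nonempty and distinct", {
  a <- buildTemplateSet(count = 3, seed = 11)
  b <- buildTemplateSet(count = 3, seed = 11)
  expect_equal(length(a), 3L)
  for (i in 1:3) {
    expect_gt(sum(a[[i]]), 0)
    expect_identical(a[[i]], b[[i]])
  }
  expect_gt(sum(a[[1]] != a[[2]]), 0)
  d <- withr::local_tempdir()
  saveTemplateSet(a, d)
  r <- loadTemplateSet(d)
  for (i in 1:3) expect_equal(unname(r[[i]]), unname(a[[i]]))
})

test_that("mask transformation honours forced and random parameters", {
  tset <- fixtureTemplates()
  tm <- tset[[1]]
  # identity path reproduces the template exactly
  id <- transformMask(tm, targetSize = 512,
                      params = list(rotate = 0, translate = c(0, 0),
                                    elastic = FALSE, scale = 1,
                                    downscale = 1))
  expect_identical(unname(id[, ]), unname(tm))
  # area scales quadratically with the global factor
  a1 <- transformMask(tm, 256, params = list(rotate = 20,
          translate = c(0, 0), elastic = FALSE, scale = 0.2,
          downscale = 0.6))
  a2 <- transformMask(tm, 256, params = list(rotate = 20,
          translate = c(0, 0), elastic = FALSE, scale = 0.9,
          downscale = 0.6))
  expect_equal(sum(a1) / sum(a2), (0.2 / 0.9)^2, tolerance = 0.1)
  # the global scale stays inside its sampling range
  s <- vapply(1:300, function(i)
    attr(transformMask(tm, 64, seed = i), "scale"), numeric(1))
  expect_gte(min(s), 0.2)
  expect_lte(max(s), 0.9)
  # area is rotation-invariant within rasterization tolerance
  base <- transformMask(tm, 256, params = list(rotate = 0,
            translate = c(0, 0), elastic = FALSE, scale = 0.8,
            downscale = 0.6))
  for (rot in c(33, 90, 145)) {
    r <- transformMask(tm, 256, params = list(rotate = rot,
           translate = c(0, 0), elastic = FALSE, scale = 0.8,
           downscale = 0.6))
    expect_equal(sum(r) / sum(base), 1, tolerance = 0.02)
  }
})

test_that("valid region excludes dark overlays and keeps bright tissue", {
  dark <- array(0, dim = c(64, 64, 3))
  expect_warning(mo <- computeValidRegion(dark), "empty")
  expect_equal(sum(mo), 0)
  bright <- array(200, dim = c(64, 64, 3))
  expect_equal(sum(computeValidRegion(bright)), 64 * 64)
  img <- generateMucosa(mucosaSpec(size = 96, seed = 6,
                                   thumbnail = "black"))
  mo <- computeValidRegion(img)
  thumb <- mo[polypseg:::thumbnailRows(96), polypseg:::thumbnailCols(96)]
  expect_gte(sum(thumb == 0), 1600 * 0.9)
})

test_that("mask placement is an AND with re-draw on failure", {
  tm <- matrix(0, 64, 64); tm[28:36, 28:36] <- 1
  ones <- matrix(1, 64, 64)
  expect_identical(placeMask(tm, ones), tm * 1)
  zeros <- matrix(0, 64, 64)
  expect_error(placeMask(tm, zeros, seed = 1), "retries")
  # partial region against a centred disc: brute-force AND oracle
  # (the disc keeps > 50% of its area, so no re-draw is triggered)
  part <- matrix(0, 64, 64); part[, 1:40] <- 1
  disc <- matrix(0, 64, 64)
  disc[(row(disc) - 32)^2 + (col(disc) - 32)^2 <= 100] <- 1
  M <- placeMask(disc, part, seed = 2)
  expect_identical(M, disc * part)
  expect_true(all(M <= part) && all(M <= disc))
})
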