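discMask <- function(size = 64, r = 10) {
  m <- matrix(0, size, size)
  ctr <- (size + 1) / 2
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- 1
  m
}

test_that("mode selection matches the 40/40/20 weights", {
  modes <- selectMode(1e5, seed = 1)
  freq <- table(factor(modes, c("patch", "texture", "hybrid"))) / 1e5
  expect_lt(abs(freq[["patch"]] - 0.4), 0.01)
  expect_lt(abs(freq[["texture"]] - 0.4), 0.01)
  expect_lt(abs(freq[["hybrid"]] - 0.2), 0.01)
  expect_true(all(selectMode(100, weights = c(1, 0, 0), seed = 2) ==
                    "patch"))
  expect_identical(selectMode(50, seed = 3), selectMode(50, seed = 3))
  expect_error(selectMode(1, weights = c(0.5, 0.5, 0.5)), "sum")
})

test_that("the transform table rows act as documented", {
  img <- generateMucosa(mucosaSpec(size = 64, seed = 1))[1:48, 1:48, ]
  off <- defaultTransformConfig(); off$prob <- 0
  expect_identical(applyPhotometricGeometric(img, seed = 1, off), img)
  one <- function(name, lo, hi) {
    cfg <- defaultTransformConfig()
    cfg$prob <- ifelse(cfg$name == name, 1, 0)
    cfg$lo[cfg$name == name] <- lo
    cfg$hi[cfg$name == name] <- hi
    cfg
  }
  # neutral gamma is the identity up to rounding
  expect_equal(applyPhotometricGeometric(img, 1, one("gamma", 1, 1)), img,
               tolerance = 1e-12)
  # intensity multiply is a pure scale pre-clipping
  const <- array(100, dim = c(16, 16, 3))
  expect_equal(applyPhotometricGeometric(const, 1,
                                         one("intensity", 2, 2)),
               array(200, dim = c(16, 16, 3)))
  # flips are exact permutations
  flipped <- applyPhotometricGeometric(img, 1, one("hflip", NA, NA))
  expect_identical(flipped, img[, 48:1, , drop = FALSE])
  # output range always valid
  out <- applyPhotometricGeometric(img, 5)
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, applyPhotometricGeometric(img, 5))
})

test_that("shadow blending darkens the rim and leaves the far field intact", {
  base <- generateMucosa(mucosaSpec(size = 64, seed = 2))
  content <- array(30, dim = c(64, 64, 3))
  M <- discMask(64, 8)
  expect_identical(shadowBlend(base, content, matrix(0, 64, 64)), base)
  out <- shadowBlend(base, content, M, sigma = 3, lambda = 0.3)
  B <- gaussianBlur(M, 3)
  far <- B == 0
  for (c in 1:3)
    expect_identical(out[, , c][far], base[, , c][far])
  # annulus around the boundary is darker than in the base image
  ctr <- (64 + 1) / 2
  d <- sqrt((row(M) - ctr)^2 + (col(M) - ctr)^2)
  ann <- d > 8 & d <= 8 + 6
  expect_lt(mean(polypseg:::luma(out)[ann]), mean(polypseg:::luma(base)[ann]))
  # lambda = 0: pixels outside the mask equal the base
  out0 <- shadowBlend(base, content, M, sigma = 3, lambda = 0)
  for (c in 1:3)
    expect_identical(out0[, , c][M == 0], base[, , c][M == 0])
})

test_that("patch synthesis composites transformed self-content", {
  I <- generateMucosa(mucosaSpec(size = 64, seed = 3))
  M <- discMask(64, 9)
  off <- defaultTransformConfig(); off$prob <- 0
  sm0 <- patchSynthesis(I, M, seed = 1, config = off, shadowLambda = 0)
  expect_identical(sampleImage(sm0), I)
  expect_equal(sampleMask(sm0), M)
  expect_identical(sampleMode(sm0), "patch")
  sm <- patchSynthesis(I, M, seed = 1)
  diffFrac <- mean(sampleImage(sm)[, , 1][M == 1] != I[, , 1][M == 1])
  expect_gte(diffFrac, 0.9)
})

test_that("texture synthesis is colour-matched and local", {
  I <- generateMucosa(mucosaSpec(size = 64, seed = 4))
  Tx <- generateTexture(textureSpec(size = 64, seed = 5))
  M <- discMask(64, 10)
  sm <- textureSynthesis(I, Tx, M, seed = 2)
  out <- sampleImage(sm)
  B <- gaussianBlur(M, 7)
  far <- B == 0
  for (c in 1:3) expect_identical(out[, , c][far], I[, , c][far])
  # masked region hue close to the reference image hue (circular distance)
  hueOf <- function(img, sel) {
    h <- polypseg:::rgb2hsvImage(img)[1, ] * 360
    h[as.vector(sel)]
  }
  circDist <- function(a, b) abs(((a - b + 180) %% 360) - 180)
  expect_lt(circDist(mean(hueOf(out, M == 1)), mean(hueOf(I, M == 1))), 30)
  # self-texture limit with transforms disabled stays close to the image
  off <- defaultTransformConfig(); off$prob <- 0
  sms <- textureSynthesis(I, I, M, seed = 3, config = off,
                          shadowLambda = 0)
  for (c in 1:3)
    expect_lt(mean(abs(sampleImage(sms)[, , c][M == 1] - I[, , c][M == 1])),
              5)
})

test_that("hybrid synthesis is a convex combination with exact limits", {
  I <- generateMucosa(mucosaSpec(size = 64, seed = 6))
  Tx <- generateTexture(textureSpec(size = 64, seed = 7))
  M <- discMask(64, 10)
  pa <- patchSynthesis(I, M, seed = 9)
  te <- textureSynthesis(I, Tx, M, seed = 9)
  hy0 <- hybridSynthesis(I, Tx, M, seed = 9, alpha = 0)
  hy1 <- hybridSynthesis(I, Tx, M, seed = 9, alpha = 1)
  expect_identical(sampleImage(hy0), sampleImage(pa))
  expect_identical(sampleImage(hy1), sampleImage(te))
  # direct midpoint evaluation without shadow
  off <- defaultTransformConfig(); off$prob <- 0
  cA <- array(100, dim = c(32, 32, 3)); cB <- array(200, dim = c(32, 32, 3))
  Md <- discMask(32, 6)
  # convexity: channel values inside the mask lie between the parents
  h <- hybridSynthesis(I, Tx, M, seed = 9, alpha = 0.5)
  ip <- sampleImage(pa); it <- sampleImage(te); ih <- sampleImage(h)
  inside <- which(gaussianBlur(M, 7) > 0 & M == 1)
  for (c in 1:3) {
    lo <- pmin(ip[, , c][inside], it[, , c][inside])
    hi <- pmax(ip[, , c][inside], it[, , c][inside])
    expect_true(all(ih[, , c][inside] >= lo - 1e-9 &
                      ih[, , c][inside] <= hi + 1e-9))
  }
  a <- vapply(1:200, function(i) hybridSynthesis(I, Tx, M, seed = i)@alpha,
              numeric(1))
  expect_gte(min(a), 0.3)
  expect_lte(max(a), 0.7)
})

test_that("the full simulator pipeline is seeded, valid and local", {
  normals <- fixtureNormals(4)
  tset <- fixtureTemplates()
  texs <- fixtureTextures(2)
  I <- normals[[2]]
  s1 <- generateSample(I, tset, texs, seed = 21)
  s2 <- generateSample(I, tset, texs, seed = 21)
  expect_identical(sampleImage(s1), sampleImage(s2))
  expect_identical(sampleMask(s1), sampleMask(s2))
  expect_identical(sampleMode(s1), sampleMode(s2))
  mo <- computeValidRegion(I)
  for (seed in 22:36) {
    s <- generateSample(I, tset, texs, seed = seed, validRegion = mo)
    M <- sampleMask(s)
    expect_gt(sum(M), 0)
    expect_true(all(M <= mo))            # lesion confined to valid tissue
    B <- gaussianBlur(M, 7)
    far <- B == 0
    img <- sampleImage(s)
    for (c in 1:3)
      expect_identical(img[, , c][far], I[, , c][far])
  }
})

test_that("mask binarization commutes with resizing within tolerance", {
  tset <- fixtureTemplates()
  M <- transformMask(tset[[1]], 128, params = list(rotate = 30,
         translate = c(0, 0), elastic = FALSE, scale = 0.8,
         downscale = 0.6))
  # route A: bilinear resize of the binary raster, then rebinarize;
  # route B: nearest-neighbour mask resize
  a <- (polypseg:::ebResizeMatrix(M, 64, 64) >= 0.5) * 1
  b <- resizeMask(M, 64, 64)
  iou <- sum(a * b) / sum(pmax(a, b))
  expect_gte(iou, 0.95)
})
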