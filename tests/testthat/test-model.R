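test_that("encoder produces the documented pyramid shapes deterministically", {
  mb <- fixtureSmokeModel()
  img <- fixtureNormals(8)[[7]]
  f <- extractFeatures(mb$model, img)
  expect_equal(dim(f$s1), c(16L, 16L, 64L))   # 1/4 res, 64 ch
  expect_equal(dim(f$s2), c(8L, 8L, 128L))    # 1/8 res, 128 ch
  expect_equal(dim(f$s3), c(4L, 4L, 256L))    # 1/16 res, 256 ch
  expect_identical(f, extractFeatures(mb$model, img))
  zero <- array(0, dim = c(64, 64, 3))
  fz <- extractFeatures(mb$model, zero)
  expect_true(all(vapply(fz, function(x) all(is.finite(x)), logical(1))))
  expect_error(extractFeatures(mb$model, array(0, dim = c(32, 32, 3))),
               "expects")
})

test_that("memory bank construction is seeded and bounded", {
  mb <- fixtureSmokeModel()
  normals <- fixtureNormals(8)
  b1 <- buildMemory(mb$model, normals, N = 5, seed = 1)
  expect_equal(length(b1), 5L)
  expect_identical(b1@indices,
                   buildMemory(mb$model, normals, N = 5, seed = 1)@indices)
  expect_error(buildMemory(mb$model, normals, N = 50, seed = 1), "exceeds")
  single <- buildMemory(mb$model, normals, N = 1, seed = 2)
  d <- bestDifferenceMap(extractFeatures(mb$model, normals[[3]]), single)
  expect_equal(unname(d$index), c(1L, 1L, 1L))
})

test_that("difference-map selection equals brute force and is nonnegative", {
  mb <- fixtureSmokeModel()
  # toy bank: hand-set 2x2x2 features, argmin vs exhaustive sums
  mkPyr <- function(k) list(s1 = array(k, dim = c(2, 2, 2)),
                            s2 = array(k / 2, dim = c(1, 1, 2)),
                            s3 = array(-k, dim = c(1, 1, 1)))
  toyBank <- new("MemoryBank",
                 pyramids = list(mkPyr(1), mkPyr(3), mkPyr(-2)),
                 indices = 1:3, inputSize = 8L)
  q <- list(s1 = array(c(2.5, 0, 1, 1, 0, 2, 1, 3), dim = c(2, 2, 2)),
            s2 = array(c(1, 2), dim = c(1, 1, 2)),
            s3 = array(0.5, dim = c(1, 1, 1)))
  d <- bestDifferenceMap(q, toyBank)
  for (s in 1:3) {
    sums <- vapply(1:3, function(i)
      sum((toyBank@pyramids[[i]][[s]] - q[[s]])^2), numeric(1))
    expect_equal(unname(d$index[s]), which.min(sums))
    expect_equal(unname(d$sums[, s]), sums)
    expect_true(all(d$maps[[s]] >= 0))
  }
  # a bank member has zero total discrepancy and selects itself
  img <- fixtureNormals(8)[[mb$bank@indices[2]]]
  dm <- bestDifferenceMap(extractFeatures(mb$model, img), mb$bank)
  expect_equal(unname(dm$index), rep(2L, 3))
  expect_equal(unname(apply(dm$sums, 2, min)), c(0, 0, 0))
})

test_that("attention cascade follows the channel-mean/product form", {
  # constant two-channel map: channel averaging
  d3 <- array(rep(c(0.2, 0.4), each = 4), dim = c(2, 2, 2))
  d2 <- array(0.5, dim = c(4, 4, 2))
  d1 <- array(2, dim = c(8, 8, 2))
  a <- spatialAttention(list(s1 = d1, s2 = d2, s3 = d3))
  expect_equal(a$m3, matrix(0.3, 2, 2))
  # constant cascade: m1 = c1 * c2 * c3
  expect_equal(a$m2, matrix(0.5 * 0.3, 4, 4))
  expect_equal(a$m1, matrix(2 * 0.5 * 0.3, 8, 8))
  # zero difference maps propagate to zero attention
  z <- spatialAttention(list(s1 = d1 * 0, s2 = d2 * 0, s3 = d3 * 0))
  expect_true(all(z$m1 == 0) && all(z$m2 == 0) && all(z$m3 == 0))
})

test_that("forward pass yields a valid, deterministic probability mask", {
  mb <- fixtureSmokeModel()
  img <- fixtureNormals(8)[[7]]
  out <- segmentForward(mb$model, img, mb$bank)
  expect_equal(dim(out$prob), c(64L, 64L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_identical(out$prob, segmentForward(mb$model, img, mb$bank)$prob)
  # zero-discrepancy propagation: a memory image gives all-zero attention,
  # hence a spatially constant output
  mem <- fixtureNormals(8)[[mb$bank@indices[1]]]
  om <- segmentForward(mb$model, mem, mb$bank)
  expect_true(all(om$attn$m1 == 0))
  expect_lt(diff(range(om$prob)), 1e-12)
})

test_that("memory order does not affect selection or output", {
  mb <- fixtureSmokeModel()
  img <- fixtureNormals(8)[[8]]
  perm <- c(3L, 5L, 1L, 4L, 2L)
  bankP <- new("MemoryBank", pyramids = mb$bank@pyramids[perm],
               indices = mb$bank@indices[perm], inputSize = 64L)
  a <- segmentForward(mb$model, img, mb$bank)
  b <- segmentForward(mb$model, img, bankP)
  expect_equal(a$dstar$maps, b$dstar$maps)
  expect_identical(a$prob, b$prob)
})

test_that("a synthetic lesion strictly increases the minimum discrepancy", {
  mb <- fixtureSmokeModel()
  normals <- fixtureNormals(8)
  tset <- fixtureTemplates()
  texs <- fixtureTextures(2)
  iMem <- mb$bank@indices[3]
  clean <- normals[[iMem]]
  sumsClean <- bestDifferenceMap(extractFeatures(mb$model, clean),
                                 mb$bank)$sums
  lesioned <- sampleImage(generateSample(clean, tset, texs, seed = 77))
  sumsLes <- bestDifferenceMap(extractFeatures(mb$model, lesioned),
                               mb$bank)$sums
  for (s in 1:3)
    expect_gt(min(sumsLes[, s]), min(sumsClean[, s]))
  # attention localisation: higher inside the lesion than outside
  M <- sampleMask(generateSample(clean, tset, texs, seed = 77))
  attn <- segmentForward(mb$model, lesioned, mb$bank)$attn
  m1full <- polypseg:::up2mat(polypseg:::up2mat(attn$m1))
  expect_gt(mean(m1full[M == 1]), mean(m1full[M == 0]))
})

test_that("parameter counts are architecture-exact", {
  ref <- buildModel(modelConfig())
  p <- countParameters(ref)
  # frozen encoder share: stem + three stages of a standard 18-layer
  # residual encoder, brute-force sum
  expect_equal(unname(p["total"] - p["trainable"]), 2782784)
  expect_equal(round(p["total"] / 1e6, 2), c(total = 19.05))
  expect_equal(round(p["trainable"] / 1e6, 2), c(trainable = 16.27))
  # msffm must keep cross-scale widths equal for elementwise addition
  sm <- buildModel(smokeModelConfig())
  ps <- countParameters(sm)
  expect_lt(ps["trainable"], 1e6)
  expect_equal(unname(ps["total"] - ps["trainable"]), 2782784)
})

test_that("fused features react to their inputs (no accidental detachment)", {
  ns <- asNamespace("polypseg")
  mb <- fixtureSmokeModel()
  img <- fixtureNormals(8)[[6]]
  pyr <- extractFeatures(mb$model, img)
  d <- bestDifferenceMap(pyr, mb$bank)
  ci <- ns$concatCI(pyr, d)
  pn <- ns$makeParamNodes(mb$model@head)
  base <- ns$msffmForward(NULL, pn, ci)
  expect_equal(dim(base$p1$val)[1:2], c(16L, 16L))
  expect_equal(dim(base$p2$val)[1:2], c(8L, 8L))
  expect_equal(dim(base$p3$val)[1:2], c(4L, 4L))
  for (s in 1:3) {
    ci2 <- ci
    ci2[[s]] <- ci2[[s]] * 2
    pert <- ns$msffmForward(NULL, pn, ci2)
    expect_gt(max(abs(pert$p1$val - base$p1$val)) +
                max(abs(pert$p3$val - base$p3$val)), 0)
  }
  zeroOut <- ns$msffmForward(NULL, pn, lapply(ci, function(x) x * 0))
  expect_true(all(is.finite(zeroOut$p1$val)))
})
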