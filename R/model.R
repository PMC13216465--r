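## The memory-augmented encoder-decoder. A frozen ResNet18-style multi-scale
## encoder produces three feature scales; an input's features are compared
## against a fixed bank of normal-image embeddings (channel-preserving
## squared differences, minimum-total-sum selection); fused, attention-
## modulated features are decoded to a probability mask by progressive x2
## upsampling.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Architecture configuration
#'
#' The reference configuration instantiates the network whose parameter
#' counts the package reports: a frozen ResNet18 stem+stages-1..3 encoder
#' (64/128/256 channels at 1/4, 1/8, 1/16 resolution) and a trainable head
#' (per-scale 3x3 fusion convolutions, coordinate-attention blocks,
#' cross-scale additive fusion, and a four-stage progressive-upsampling
#' decoder).
#'
#' @param inputSize Input side length in pixels (multiple of 32).
#' @param msffmWidth Common channel width of the fused scales.
#' @param caMid Bottleneck width of the coordinate-attention blocks.
#' @param entryWidth Width of the decoder entry convolution.
#' @param decoderWidths Widths of the four decoder stages.
#' @param memorySize Number of normal prototypes in the memory bank.
#' @param encoderSeed,headSeed Seeds of the (deterministic) initialisation.
#' @return Configuration list.
#' @export
modelConfig <- function(inputSize = 256L, msffmWidth = 512L, caMid = 160L,
                        entryWidth = 512L,
                        decoderWidths = c(512L, 256L, 128L, 70L),
                        memorySize = 30L, encoderSeed = 73L,
                        headSeed = 74L) {
  if (inputSize %% 32 != 0) stop("inputSize must be a multiple of 32")
  list(inputSize = as.integer(inputSize),
       msffmWidth = as.integer(msffmWidth), caMid = as.integer(caMid),
       entryWidth = as.integer(entryWidth),
       decoderWidths = as.integer(decoderWidths),
       memorySize = as.integer(memorySize),
       encoderSeed = as.integer(encoderSeed),
       headSeed = as.integer(headSeed),
       encoderChannels = c(64L, 128L, 256L))
}

#' Reduced-width configuration for CPU-scale smoke training
#' @param inputSize Input side length (default 64).
#' @return Configuration list (see [modelConfig()]).
#' @export
smokeModelConfig <- function(inputSize = 64L) {
  modelConfig(inputSize = inputSize, msffmWidth = 32L, caMid = 16L,
              entryWidth = 32L, decoderWidths = c(32L, 24L, 16L, 8L))
}

## parameter constructors (He-normal fan-in init); conv weights are stored
## as (Cin*k*k) x Cout matrices matching the im2col kernels
makeConv <- function(k, cin, cout, bias = TRUE) {
  W <- matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  out <- list(W = W, k = as.integer(k))
  if (bias) out$b <- numeric(cout)
  out
}

makeNorm <- function(c) list(g = rep(1, c), be = numeric(c))

## batch-norm of the frozen encoder: affine parameters plus fixed running
## statistics (buffers, not counted as parameters)
makeBN <- function(c) list(g = rep(1, c), be = numeric(c),
                           mu = numeric(c), v = rep(1, c))

buildEncoderParams <- function(seed) {
  withSeed(seed, {
    basicBlock <- function(cin, cout, down) {
      b <- list(c1 = makeConv(3, cin, cout, bias = FALSE), n1 = makeBN(cout),
                c2 = makeConv(3, cout, cout, bias = FALSE), n2 = makeBN(cout))
      if (down)
        b$dc <- makeConv(1, cin, cout, bias = FALSE)
      if (down) b$dn <- makeBN(cout)
      b
    }
    list(
      conv1 = makeConv(7, 3, 64, bias = FALSE), bn1 = makeBN(64),
      l1b1 = basicBlock(64, 64, FALSE), l1b2 = basicBlock(64, 64, FALSE),
      l2b1 = basicBlock(64, 128, TRUE), l2b2 = basicBlock(128, 128, FALSE),
      l3b1 = basicBlock(128, 256, TRUE), l3b2 = basicBlock(256, 256, FALSE))
  })
}

buildHeadParams <- function(cfg) {
  W <- cfg$msffmWidth; mid <- cfg$caMid; E <- cfg$entryWidth
  D <- cfg$decoderWidths; CC <- cfg$encoderChannels
  withSeed(cfg$headSeed, {
    ca <- function() list(
      W1 = matrix(rnorm(W * mid, sd = sqrt(2 / W)), W, mid),
      b1 = numeric(mid), n1 = makeNorm(mid),
      Wh = matrix(rnorm(mid * W, sd = sqrt(2 / mid)), mid, W),
      bh = numeric(W),
      Ww = matrix(rnorm(mid * W, sd = sqrt(2 / mid)), mid, W),
      bw = numeric(W))
    h <- list(
      convR1 = makeConv(3, 2 * CC[1], W), nR1 = makeNorm(W), ca1 = ca(),
      convR2 = makeConv(3, 2 * CC[2], W), nR2 = makeNorm(W), ca2 = ca(),
      convR3 = makeConv(3, 2 * CC[3], W), nR3 = makeNorm(W), ca3 = ca(),
      convU3 = makeConv(3, W, W), nU3 = makeNorm(W),
      convU2 = makeConv(3, W, W), nU2 = makeNorm(W),
      entry = makeConv(3, W, E), nE = makeNorm(E),
      dec1 = makeConv(3, E, D[1]), nD1 = makeNorm(D[1]),
      skip2 = makeConv(1, W, D[1]),
      dec2 = makeConv(3, D[1], D[2]), nD2 = makeNorm(D[2]),
      skip1 = makeConv(1, W, D[2]),
      dec3 = makeConv(3, D[2], D[3]), nD3 = makeNorm(D[3]),
      dec4 = makeConv(3, D[3], D[4]), nD4 = makeNorm(D[4]),
      final = makeConv(1, D[4], 1))
    h
  })
}

#' Instantiate the segmentation network
#'
#' Builds the frozen encoder and the trainable head from a configuration,
#' with deterministic seeded initialisation.
#'
#' @param config A [modelConfig()].
#' @return A [SegModel-class].
#' @export
buildModel <- function(config = modelConfig()) {
  new("SegModel", config = config,
      encoder = buildEncoderParams(config$encoderSeed),
      head = buildHeadParams(config))
}

## recursively sum parameter element counts; encoder BN running statistics
## (mu, v) are buffers, not parameters
countList <- function(x, skip = c("mu", "v", "k")) {
  if (is.list(x)) {
    nm <- names(x)
    sum(vapply(seq_along(x),
               function(i) if (nm[i] %in% skip) 0 else countList(x[[i]],
                                                                 skip),
               numeric(1)))
  } else length(x)
}

#' Count model parameters
#'
#' @param model A [SegModel-class].
#' @return Named vector `c(total, trainable)`; trainable excludes the
#'   frozen encoder.
#' @export
countParameters <- function(model) {
  enc <- countList(model@encoder)
  head <- countList(model@head)
  c(total = enc + head, trainable = head)
}

## ---- frozen encoder forward (no autodiff needed) ----

## hook: environment with $target (BN name) and accumulators; when the
## named BN is reached, per-channel moments of its input are collected
bnEval <- function(x, bn, eps = 1e-5, hook = NULL, name = NULL) {
  if (!is.null(hook) && identical(hook$target, name)) {
    M <- x; dim(M) <- c(dim(x)[1] * dim(x)[2], dim(x)[3])
    hook$s <- hook$s + colSums(M)
    hook$s2 <- hook$s2 + colSums(M * M)
    hook$n <- hook$n + nrow(M)
  }
  sc <- bn$g / sqrt(bn$v + eps)
  sh <- bn$be - bn$mu * sc
  for (c in seq_len(dim(x)[3])) x[, , c] <- x[, , c] * sc[c] + sh[c]
  x
}

convF <- function(x, cv, stride = 1L, pad = (cv$k - 1L) %/% 2L) {
  b <- if (is.null(cv$b)) numeric(ncol(cv$W)) else cv$b
  conv2d_fwd_cpp(x, cv$W, b, cv$k, stride, pad)
}

blockF <- function(x, blk, stride = 1L, hook = NULL, name = NULL) {
  y <- pmax(bnEval(convF(x, blk$c1, stride = stride), blk$n1, hook = hook,
                   name = paste0(name, ".n1")), 0)
  y <- bnEval(convF(y, blk$c2), blk$n2, hook = hook,
              name = paste0(name, ".n2"))
  skip <- if (is.null(blk$dc)) x else
    bnEval(convF(x, blk$dc, stride = stride, pad = 0L), blk$dn,
           hook = hook, name = paste0(name, ".dn"))
  pmax(y + skip, 0)
}

#' Extract the multi-scale feature pyramid of an image
#'
#' Normalises the image (channel means/sds of the standard natural-image
#' convention after scaling to [0, 1]) and runs the frozen encoder,
#' returning stage-1..3 activations: 64, 128 and 256 channels at 1/4, 1/8
#' and 1/16 of the input resolution.
#'
#' @param model A [SegModel-class].
#' @param image RGB raster of size `config$inputSize`.
#' @param hook Internal (normalisation-statistics collection).
#' @return List of three feature arrays (`s1`, `s2`, `s3`).
#' @export
extractFeatures <- function(model, image, hook = NULL) {
  assertImage(image)
  sz <- model@config$inputSize
  if (!all(dim(image)[1:2] == sz))
    stop("encoder expects a ", sz, "x", sz, " input")
  x <- image / 255
  for (c in 1:3) x[, , c] <- (x[, , c] - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
  e <- model@encoder
  x <- pmax(bnEval(convF(x, e$conv1, stride = 2L, pad = 3L), e$bn1,
                   hook = hook, name = "bn1"), 0)
  x <- maxpool3x3s2_cpp(x)
  x <- blockF(blockF(x, e$l1b1, hook = hook, name = "l1b1"),
              e$l1b2, hook = hook, name = "l1b2")
  s1 <- x
  x <- blockF(blockF(x, e$l2b1, stride = 2L, hook = hook, name = "l2b1"),
              e$l2b2, hook = hook, name = "l2b2")
  s2 <- x
  x <- blockF(blockF(x, e$l3b1, stride = 2L, hook = hook, name = "l3b1"),
              e$l3b2, hook = hook, name = "l3b2")
  list(s1 = s1, s2 = s2, s3 = x)
}

## names of the encoder BN layers in forward order, with the slot path of
## each ((block, bn) pairs)
encoderBNOrder <- function() {
  out <- list(c("bn1", "bn1"))
  for (blk in c("l1b1", "l1b2", "l2b1", "l2b2", "l3b1", "l3b2"))
    for (n in c("n1", "n2", "dn"))
      out[[length(out) + 1]] <- c(paste0(blk, ".", n), blk, n)
  out
}

#' Calibrate encoder normalisation statistics on normal images
#'
#' Sets the running mean/variance of every encoder normalisation layer to
#' the statistics observed on a set of polyp-free images (layer by layer,
#' in forward order, so each layer is calibrated under the already
#' calibrated layers before it). With an untrained encoder this keeps
#' activations well-scaled through the residual stages, which sharpens the
#' feature-discrepancy contrast the memory mechanism relies on.
#'
#' @param model A [SegModel-class].
#' @param images List of RGB rasters at the model input size.
#' @return The calibrated model.
#' @export
calibrateEncoder <- function(model, images) {
  for (entry in encoderBNOrder()) {
    name <- entry[1]
    bn <- if (length(entry) == 2) model@encoder[[entry[2]]]
          else model@encoder[[entry[2]]][[entry[3]]]
    if (is.null(bn)) next  # blocks without a downsample path
    hook <- new.env(parent = emptyenv())
    hook$target <- name
    hook$s <- numeric(length(bn$mu))
    hook$s2 <- numeric(length(bn$mu))
    hook$n <- 0
    for (img in images) extractFeatures(model, img, hook = hook)
    mu <- hook$s / hook$n
    v <- pmax(hook$s2 / hook$n - mu^2, 1e-8)
    bn$mu <- mu
    bn$v <- v
    if (length(entry) == 2) model@encoder[[entry[2]]] <- bn
    else model@encoder[[entry[2]]][[entry[3]]] <- bn
  }
  model
}

#' Build the fixed memory bank of normal prototypes
#'
#' Randomly selects `N` polyp-free images (without replacement, seeded),
#' encodes each to a feature pyramid, and freezes the result.
#'
#' @param model A [SegModel-class].
#' @param normals List of normal RGB rasters at the model input size.
#' @param N Number of prototypes (default from the model config).
#' @param seed Selection seed.
#' @return A [MemoryBank-class].
#' @export
buildMemory <- function(model, normals, N = model@config$memorySize,
                        seed = 0L) {
  if (N > length(normals))
    stop("N = ", N, " exceeds the ", length(normals), " available normals")
  idx <- withSeed(seed, sample.int(length(normals), N))
  new("MemoryBank",
      pyramids = lapply(idx, function(i) extractFeatures(model,
                                                         normals[[i]])),
      indices = as.integer(idx), inputSize = model@config$inputSize)
}

#' Select the best-matching difference maps against the memory bank
#'
#' For each scale, the candidate difference map against prototype i is the
#' channel-preserving element-wise squared difference; the selected map is
#' the candidate with the minimum total sum over all elements (the closest
#' normal prototype).
#'
#' @param pyramid Feature pyramid of the input image.
#' @param bank A [MemoryBank-class].
#' @return List with `maps` (selected difference map per scale), `index`
#'   (selected prototype per scale) and `sums` (N x 3 matrix of totals).
#' @export
bestDifferenceMap <- function(pyramid, bank) {
  N <- length(bank@pyramids)
  scales <- c("s1", "s2", "s3")
  sums <- matrix(0, N, 3, dimnames = list(NULL, scales))
  for (i in seq_len(N))
    for (s in 1:3)
      sums[i, s] <- sum((bank@pyramids[[i]][[s]] - pyramid[[s]])^2)
  idx <- apply(sums, 2, which.min)
  maps <- lapply(1:3, function(s)
    (bank@pyramids[[idx[s]]][[scales[s]]] - pyramid[[scales[s]]])^2)
  names(maps) <- scales
  list(maps = maps, index = idx, sums = sums)
}

channelMean <- function(x) {
  m <- x[, , 1] * 0
  for (c in seq_len(dim(x)[3])) m <- m + x[, , c]
  m / dim(x)[3]
}

up2mat <- function(m) upsample2x_fwd_cpp(array(m, dim = c(dim(m), 1L)))[, , 1]

#' Cascaded spatial attention maps from the selected difference maps
#'
#' The coarsest attention map is the channel mean of the coarsest selected
#' difference map; each finer map is its own channel mean multiplied
#' element-wise by the bilinear x2 upsampling of the coarser map.
#'
#' @param dstar `maps` element of [bestDifferenceMap()].
#' @return List of single-channel maps `m1`, `m2`, `m3` (finest first).
#' @export
spatialAttention <- function(dstar) {
  m3 <- channelMean(dstar$s3)
  m2 <- channelMean(dstar$s2) * up2mat(m3)
  m1 <- channelMean(dstar$s1) * up2mat(m2)
  list(m1 = m1, m2 = m2, m3 = m3)
}

## ---- trainable head ----

## wrap head parameter arrays in autodiff nodes (values are shared, grads
## accumulate on the nodes)
makeParamNodes <- function(params) {
  rapply(params, agNode, how = "replace",
         classes = c("numeric", "matrix", "array", "integer"))
}

harvestParamValues <- function(nodes) {
  rapply(nodes, function(n) n$val, how = "replace", classes = "environment")
}

## conv + instance norm + relu block on the tape
blockCNR <- function(tape, x, cv, nrm) {
  agReLU(tape, agNormChan(tape, agConv(tape, x, cv$W, cv$b, cv$k$val),
                          nrm$g, nrm$be))
}

caBlock <- function(tape, x, ca) {
  H <- dim(x$val)[1]; Wd <- dim(x$val)[2]
  zh <- agMeanW(tape, x)
  zw <- agMeanH(tape, x)
  y <- agRbind(tape, zh, zw)
  y <- agReLU(tape, agNormCols(tape,
        agAddBiasCols(tape, agMatmul(tape, y, ca$W1), ca$b1),
        ca$n1$g, ca$n1$be))
  ah <- agSigmoid(tape, agAddBiasCols(tape,
          agMatmul(tape, agRows(tape, y, seq_len(H)), ca$Wh), ca$bh))
  aw <- agSigmoid(tape, agAddBiasCols(tape,
          agMatmul(tape, agRows(tape, y, H + seq_len(Wd)), ca$Ww), ca$bw))
  agScaleHW(tape, x, ah, aw)
}

#' Multi-scale feature fusion on the trainable head
#'
#' Per scale: 3x3 convolution (semantic harmonisation), coordinate
#' attention; coarser scales are upsampled, convolved and added
#' element-wise into finer scales.
#'
#' @param tape Autodiff tape (or `NULL` for inference).
#' @param pn Head parameter nodes.
#' @param ci List of three concatenated feature arrays (input features ++
#'   selected difference maps along channels), finest first.
#' @return List of fused feature nodes `p1`, `p2`, `p3`.
#' @keywords internal
msffmForward <- function(tape, pn, ci) {
  a1 <- caBlock(tape, blockCNR(tape, agNode(ci[[1]]), pn$convR1, pn$nR1),
                pn$ca1)
  a2 <- caBlock(tape, blockCNR(tape, agNode(ci[[2]]), pn$convR2, pn$nR2),
                pn$ca2)
  a3 <- caBlock(tape, blockCNR(tape, agNode(ci[[3]]), pn$convR3, pn$nR3),
                pn$ca3)
  p3 <- a3
  p2 <- agAdd(tape, a2, blockCNR(tape, agUp2(tape, p3), pn$convU3, pn$nU3))
  p1 <- agAdd(tape, a1, blockCNR(tape, agUp2(tape, p2), pn$convU2, pn$nU2))
  list(p1 = p1, p2 = p2, p3 = p3)
}

headForward <- function(tape, pn, ci, attn) {
  p <- msffmForward(tape, pn, ci)
  # attention magnitudes vary by orders of magnitude across images; the
  # parameter-free normalisation keeps the spatial pattern while removing
  # the per-image scale, stabilising shared-weight gradients
  f1 <- agNormChan0(tape, agMulMap(tape, p$p1, attn$m1))
  f2 <- agNormChan0(tape, agMulMap(tape, p$p2, attn$m2))
  f3 <- agNormChan0(tape, agMulMap(tape, p$p3, attn$m3))
  x <- blockCNR(tape, f3, pn$entry, pn$nE)
  x <- blockCNR(tape, agUp2(tape, x), pn$dec1, pn$nD1)
  x <- agAdd(tape, x, agConv(tape, f2, pn$skip2$W, pn$skip2$b, 1L))
  x <- blockCNR(tape, agUp2(tape, x), pn$dec2, pn$nD2)
  x <- agAdd(tape, x, agConv(tape, f1, pn$skip1$W, pn$skip1$b, 1L))
  x <- blockCNR(tape, agUp2(tape, x), pn$dec3, pn$nD3)
  x <- blockCNR(tape, agUp2(tape, x), pn$dec4, pn$nD4)
  agSigmoid(tape, agConv(tape, x, pn$final$W, pn$final$b, 1L))
}

## concatenate input features and difference maps along channels; each
## channel is standardised per image (zero mean, unit variance) so the
## head sees comparable scales regardless of the image's overall
## discrepancy magnitude
concatCI <- function(pyramid, dstar) {
  lapply(1:3, function(s) {
    a <- pyramid[[s]]; b <- dstar$maps[[s]]
    d <- dim(a)
    x <- array(c(a, b), dim = c(d[1], d[2], 2 * d[3]))
    M <- x; dim(M) <- c(d[1] * d[2], 2 * d[3])
    M <- sweep(M, 2, colMeans(M))
    sdc <- sqrt(colMeans(M * M) + 1e-5)
    M <- sweep(M, 2, sdc, "/")
    dim(M) <- dim(x)
    M
  })
}

#' Full forward pass: image to probability mask
#'
#' Encoder features, memory comparison, fusion, attention modulation and
#' progressive decoding. Deterministic in evaluation.
#'
#' @param model A [SegModel-class].
#' @param image RGB raster at the model input size.
#' @param bank A [MemoryBank-class].
#' @param pn Optional pre-built head parameter nodes (training).
#' @param tape Optional autodiff tape (training).
#' @return List with `prob` (probability matrix in [0, 1]), `probNode`,
#'   `dstar`, `attn`.
#' @export
segmentForward <- function(model, image, bank, pn = NULL, tape = NULL) {
  pyr <- extractFeatures(model, image)
  dstar <- bestDifferenceMap(pyr, bank)
  attn <- spatialAttention(dstar$maps)
  if (is.null(pn)) pn <- makeParamNodes(model@head)
  out <- headForward(tape, pn, concatCI(pyr, dstar), attn)
  list(prob = out$val[, , 1], probNode = out, dstar = dstar, attn = attn)
}
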