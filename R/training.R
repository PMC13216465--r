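## One-class training: batches mix polyp-free images (all-zero masks) with
## simulator-generated lesion pairs; the head is optimised with focal loss
## under SGD + cosine-annealed learning rate; model selection keeps the
## checkpoint maximising (IoU + Dice)/2 on a held-out validation split.

#' Pixel-wise focal loss
#'
#' `L = mean( -alpha * (1 - p_t)^gamma * log(p_t) )` with
#' `p_t = shat` where the ground truth is 1 and `1 - shat` where it is 0.
#' Down-weights easy pixels, countering the extreme foreground/background
#' imbalance of small lesions.
#'
#' @param shat Predicted probability raster in [0, 1].
#' @param s Binary ground-truth raster.
#' @param alpha Weighting factor (default 1).
#' @param gamma Focusing parameter (default 4).
#' @param eps Clamp bound for the probabilities.
#' @return Scalar loss (mean over pixels).
#' @export
focalLoss <- function(shat, s, alpha = 1, gamma = 4, eps = 1e-7) {
  if (!all(dim(shat) == dim(s))) stop("shape mismatch")
  p <- pmin(pmax(shat, eps), 1 - eps)
  pt <- ifelse(s == 1, p, 1 - p)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

## analytic d(loss)/d(shat) for the backward pass
focalLossGrad <- function(shat, s, alpha = 1, gamma = 4, eps = 1e-7) {
  p <- pmin(pmax(shat, eps), 1 - eps)
  n <- length(p)
  gPos <- alpha * (gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p)
  gNeg <- -alpha * (gamma * p^(gamma - 1) * log(1 - p) - p^gamma / (1 - p))
  ifelse(s == 1, gPos, gNeg) / n
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr0 * (1 + cos(pi * e / total)) / 2`: starts at `lr0`, decays
#' smoothly to 0 at the final epoch.
#'
#' @param epoch Schedule index in `[0, total]`.
#' @param total Total number of epochs.
#' @param lr0 Initial learning rate.
#' @return Learning rate.
#' @export
cosineLR <- function(epoch, total, lr0 = 0.01) {
  if (total <= 0) stop("total must be positive")
  lr0 * (1 + cos(pi * epoch / total)) / 2
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 256x256 inputs, batch size 8,
#' up to 5000 epochs, SGD with momentum 0.9 and weight decay 3e-4, initial
#' learning rate 0.01 with cosine annealing, focal loss (alpha 1, gamma 4),
#' a 20% validation split and half-synthetic batches.
#'
#' @param inputSize Training resolution.
#' @param batchSize Images per batch.
#' @param epochs Maximum epochs.
#' @param lr0 Initial learning rate.
#' @param momentum,weightDecay SGD hyperparameters.
#' @param focalAlpha,focalGamma Focal-loss hyperparameters.
#' @param valFraction Fraction of normals held out for validation.
#' @param syntheticFraction Fraction of synthetic pairs per batch.
#' @param stepsPerEpoch Batches per epoch (`NULL`: one pass over training
#'   normals).
#' @param evalEvery Validate every this many epochs.
#' @param valPairs Number of held-out synthetic validation pairs.
#' @param synPoolSize Bounded pool of pre-generated synthetic pairs that
#'   batches draw from (`NULL`: a fresh pair is simulated for every batch
#'   slot). A bounded pool lets short runs revisit each lesion often
#'   enough to consolidate; the reference protocol's epoch budget does not
#'   need it.
#' @param calibrationImages Number of training normals used to calibrate
#'   the encoder normalisation statistics (0 disables).
#' @param seed Master seed.
#' @return Configuration list.
#' @export
trainConfig <- function(inputSize = 256L, batchSize = 8L, epochs = 5000L,
                        lr0 = 0.01, momentum = 0.9, weightDecay = 3e-4,
                        focalAlpha = 1, focalGamma = 4, valFraction = 0.2,
                        syntheticFraction = 0.5, stepsPerEpoch = NULL,
                        evalEvery = 1L, valPairs = 8L, synPoolSize = NULL,
                        calibrationImages = 20L, seed = 1L) {
  stopifnot(valFraction > 0, valFraction < 1, lr0 > 0,
            syntheticFraction >= 0, syntheticFraction <= 1, batchSize >= 2)
  list(inputSize = as.integer(inputSize), batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), lr0 = lr0, momentum = momentum,
       weightDecay = weightDecay, focalAlpha = focalAlpha,
       focalGamma = focalGamma, valFraction = valFraction,
       syntheticFraction = syntheticFraction,
       stepsPerEpoch = stepsPerEpoch, evalEvery = as.integer(evalEvery),
       valPairs = as.integer(valPairs),
       synPoolSize = if (is.null(synPoolSize)) NULL
                     else as.integer(synPoolSize),
       calibrationImages = as.integer(calibrationImages),
       seed = as.integer(seed))
}

#' Compose one training batch
#'
#' Draws `round(batch * syntheticFraction)` simulator pairs and fills the
#' rest with normal images paired with all-zero masks; everything is
#' resized to the target resolution (masks nearest-neighbour, rebinarized).
#'
#' @param normals List of normal RGB rasters.
#' @param simpoFun Function `(seed) ->` [SyntheticSample-class].
#' @param batch Batch size.
#' @param syntheticFraction Fraction of synthetic pairs.
#' @param targetSize Training resolution.
#' @param seed Batch seed.
#' @return List with `images`, `masks`, `synthetic` (logical).
#' @export
makeBatch <- function(normals, simpoFun, batch = 8L,
                      syntheticFraction = 0.5, targetSize = 256L,
                      seed = 0L) {
  if (length(normals) == 0) stop("no normal images")
  if (batch < 2) stop("batch must be >= 2")
  nSyn <- round(batch * syntheticFraction)
  fit <- function(img) {
    if (all(dim(img)[1:2] == targetSize)) img
    else resizeImage(img, targetSize, targetSize)
  }
  images <- vector("list", batch)
  masks <- vector("list", batch)
  synthetic <- c(rep(TRUE, nSyn), rep(FALSE, batch - nSyn))
  pickIdx <- withSeed(deriveSeed(seed, "batchpick"),
                      sample.int(length(normals), batch, replace = TRUE))
  for (i in seq_len(batch)) {
    if (synthetic[i]) {
      sm <- simpoFun(deriveSeed(seed, "batchsyn", i))
      images[[i]] <- fit(sampleImage(sm))
      m <- sampleMask(sm)
      masks[[i]] <- if (all(dim(m) == targetSize)) m
                    else resizeMask(m, targetSize, targetSize)
    } else {
      images[[i]] <- fit(normals[[pickIdx[i]]])
      masks[[i]] <- matrix(0, targetSize, targetSize)
    }
  }
  list(images = images, masks = masks, synthetic = synthetic,
       normalIdx = ifelse(synthetic, NA_integer_, pickIdx))
}

## SGD with momentum and decoupled-from-nothing weight decay (decay added
## to the gradient, the classical convention)
sgdInit <- function(pn) rapply(pn, function(n) n$val * 0, how = "replace",
                               classes = "environment")

sgdStep <- function(pn, vel, lr, momentum, wd) {
  step <- function(node, v) {
    if (is.null(node$grad)) return(v)
    v <- momentum * v + node$grad + wd * node$val
    node$val <- node$val - lr * v
    node$grad <- NULL
    v
  }
  walk <- function(p, v) {
    if (is.environment(p)) return(step(p, v))
    for (i in seq_along(p)) v[[i]] <- walk(p[[i]], v[[i]])
    v
  }
  walk(pn, vel)
}

zeroGrads <- function(pn) {
  rapply(pn, function(n) { n$grad <- NULL; NULL }, how = "unlist",
         classes = "environment")
  invisible(NULL)
}

## head forward on precomputed (ci, attn); returns prob matrix
headEval <- function(pn, ci, attn) {
  headForward(NULL, pn, ci, attn)$val[, , 1]
}

## mean IoU/Dice over validation pairs; images with an empty ground truth
## (pure normals) are scored by specificity (1 - false-positive fraction):
## the overlap ratios are degenerate there - one stray pixel would score 0
## while a pristine empty prediction scores 1 - which would make an
## untrained all-background model unbeatable during model selection
evalPairs <- function(pn, pairs, threshold = 0.5) {
  ious <- dices <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    prob <- headEval(pn, pairs[[i]]$ci, pairs[[i]]$attn)
    pred <- (prob >= threshold) * 1
    if (sum(pairs[[i]]$mask) == 0) {
      spec <- 1 - mean(pred)
      ious[i] <- spec; dices[i] <- spec
    } else {
      m <- iouDice(confusionCounts(pred, pairs[[i]]$mask))
      ious[i] <- m["iou"]; dices[i] <- m["dice"]
    }
  }
  c(iou = mean(ious), dice = mean(dices))
}

#' Reduced-scale training configuration for CPU smoke runs
#'
#' 30 epochs of 8 batches at 128x128 (64 px fixture crops are upscaled by
#' the loader), drawing from a bounded pool of 48 pre-generated synthetic
#' pairs; pairs with [smokeModelConfig()]. The bounded pool lets the short
#' epoch budget revisit each lesion often enough to consolidate.
#'
#' @param seed Master seed.
#' @param epochs Number of epochs.
#' @return Configuration list (see [trainConfig()]).
#' @export
smokeTrainConfig <- function(seed = 1L, epochs = 30L) {
  trainConfig(inputSize = 128L, epochs = as.integer(epochs),
              stepsPerEpoch = 8L, valPairs = 12L, evalEvery = 3L,
              synPoolSize = 48L, calibrationImages = 16L, seed = seed)
}

#' Train the segmentation head
#'
#' Splits the normals into train/validation, builds the memory bank from
#' training normals, generates fixed held-out synthetic validation pairs,
#' and optimises the head on mixed batches. The best checkpoint by mean
#' validation segmentation score `(IoU + Dice)/2` is retained; the log
#' records the untrained (epoch 0) score first.
#'
#' @param normals Named list of normal RGB rasters (any resolution).
#' @param templates A [MaskTemplateSet-class].
#' @param textures List of texture rasters.
#' @param config A [trainConfig()].
#' @param arch A [modelConfig()] (use [smokeModelConfig()] for CPU runs).
#' @param verbose Print per-epoch progress.
#' @return A [SegCheckpoint-class].
#' @export
trainModel <- function(normals, templates, textures,
                       config = trainConfig(), arch = modelConfig(),
                       verbose = FALSE) {
  stopifnot(length(normals) >= 5)
  sz <- config$inputSize
  if (sz != arch$inputSize)
    stop("trainConfig and modelConfig input sizes differ")
  if (is.null(names(normals)))
    names(normals) <- sprintf("normal_%04d", seq_along(normals))
  nVal <- max(1L, round(config$valFraction * length(normals)))
  valIdx <- withSeed(deriveSeed(config$seed, "valsplit"),
                     sample.int(length(normals), nVal))
  trainNames <- names(normals)[-valIdx]
  valNames <- names(normals)[valIdx]
  fit <- function(img) if (all(dim(img)[1:2] == sz)) img
                       else resizeImage(img, sz, sz)
  ## lesions are simulated at the native resolution of the source images
  ## (shadow and blur scales are defined in source pixels), then the pair
  ## is resized to the training resolution
  trainRaw <- normals[-valIdx]
  valRaw <- normals[valIdx]
  trainImgs <- lapply(trainRaw, fit)
  valImgs <- lapply(valRaw, fit)

  model <- buildModel(arch)
  if (config$calibrationImages > 0)
    model <- calibrateEncoder(model,
      trainImgs[seq_len(min(config$calibrationImages,
                            length(trainImgs)))])
  bank <- buildMemory(model, trainImgs,
                      min(arch$memorySize, length(trainImgs)),
                      seed = deriveSeed(config$seed, "memory"))
  pn <- makeParamNodes(model@head)
  vel <- sgdInit(pn)

  simpoFun <- function(seed, pool) {
    i <- withSeed(deriveSeed(seed, "imgpick"), sample.int(length(pool), 1))
    generateSample(pool[[i]], templates, textures, seed = seed)
  }
  ## precompute encoder-side context (features, difference maps, attention)
  prepare <- function(img, mask) {
    pyr <- extractFeatures(model, img)
    dstar <- bestDifferenceMap(pyr, bank)
    list(ci = concatCI(pyr, dstar), attn = spatialAttention(dstar$maps),
         mask = mask)
  }
  valPairs <- lapply(seq_len(config$valPairs), function(i) {
    sm <- simpoFun(deriveSeed(config$seed, "valpair", i), valRaw)
    prepare(fit(sampleImage(sm)),
            resizeMask(sampleMask(sm), sz, sz))
  })
  ## normal validation images contribute all-zero masks
  valPairsAll <- c(valPairs, lapply(valImgs[seq_len(min(4,
                     length(valImgs)))], function(v)
    prepare(v, matrix(0, sz, sz))))
  trainCache <- lapply(trainImgs, function(img)
    prepare(img, matrix(0, sz, sz)))
  ## bounded pool of pre-generated synthetic training pairs (optional)
  synPool <- if (!is.null(config$synPoolSize))
    lapply(seq_len(config$synPoolSize), function(i) {
      sm <- simpoFun(deriveSeed(config$seed, "pool", i), trainRaw)
      prepare(fit(sampleImage(sm)), resizeMask(sampleMask(sm), sz, sz))
    })

  steps <- if (is.null(config$stepsPerEpoch))
    max(1L, ceiling(length(trainImgs) / config$batchSize))
  else config$stepsPerEpoch

  ## validation: selection score over synthetic + normal pairs; the
  ## reported IoU/Dice are on the held-out synthetic pairs
  validate <- function() {
    syn <- evalPairs(pn, valPairs)
    nrm <- if (length(valPairsAll) > length(valPairs))
      evalPairs(pn, valPairsAll[-seq_along(valPairs)]) else NULL
    sel <- if (is.null(nrm)) mean(syn)
           else mean(c(syn, nrm))
    list(syn = syn, sel = sel)
  }
  v0 <- validate()
  log <- data.frame(epoch = 0L, lr = NA_real_, loss = NA_real_,
                    valIoU = v0$syn["iou"], valDice = v0$syn["dice"],
                    selScore = v0$sel)
  best <- list(score = v0$sel, head = harvestParamValues(pn),
               epoch = 0L, iou = v0$syn["iou"], dice = v0$syn["dice"])

  for (epoch in seq_len(config$epochs)) {
    lr <- cosineLR(epoch - 1, config$epochs, config$lr0)
    lossAcc <- 0
    for (step in seq_len(steps)) {
      bseed <- deriveSeed(config$seed, "batch",
                          (epoch - 1) * steps + step)
      nSyn <- round(config$batchSize * config$syntheticFraction)
      ## assemble batch contexts: synthetic pairs (pooled or fresh) plus
      ## cached normal images with all-zero masks
      ctxs <- withSeed(bseed, {
        syn <- if (is.null(synPool)) {
          lapply(seq_len(nSyn), function(i) {
            sm <- simpoFun(deriveSeed(bseed, "fresh", i), trainRaw)
            prepare(fit(sampleImage(sm)),
                    resizeMask(sampleMask(sm), sz, sz))
          })
        } else synPool[sample.int(length(synPool), nSyn)]
        nrm <- trainCache[sample.int(length(trainCache),
                                     config$batchSize - nSyn,
                                     replace = TRUE)]
        c(syn, nrm)
      })
      zeroGrads(pn)
      bloss <- 0
      for (ctx in ctxs) {
        tape <- agTape()
        out <- headForward(tape, pn, ctx$ci, attn = ctx$attn)
        prob <- out$val[, , 1]
        L <- focalLoss(prob, ctx$mask, config$focalAlpha,
                       config$focalGamma)
        if (!is.finite(L))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        bloss <- bloss + L / length(ctxs)
        g <- focalLossGrad(prob, ctx$mask, config$focalAlpha,
                           config$focalGamma) / length(ctxs)
        agBackward(tape, out, array(g, dim = c(dim(prob), 1L)))
      }
      vel <- sgdStep(pn, vel, lr, config$momentum, config$weightDecay)
      lossAcc <- lossAcc + bloss / steps
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = lossAcc,
                      valIoU = NA_real_, valDice = NA_real_,
                      selScore = NA_real_)
    if (epoch %% config$evalEvery == 0 || epoch == config$epochs) {
      v <- validate()
      row$valIoU <- v$syn["iou"]; row$valDice <- v$syn["dice"]
      row$selScore <- v$sel
      if (v$sel > best$score) {
        best <- list(score = v$sel, head = harvestParamValues(pn),
                     epoch = epoch, iou = v$syn["iou"],
                     dice = v$syn["dice"])
      }
      if (verbose)
        message(sprintf(
          "epoch %3d lr %.5f loss %.5f synIoU %.3f synDice %.3f sel %.3f",
          epoch, lr, lossAcc, v$syn["iou"], v$syn["dice"], v$sel))
    } else if (verbose) {
      message(sprintf("epoch %3d lr %.5f loss %.5f", epoch, lr, lossAcc))
    }
    log <- rbind(log, row)
  }
  bestModel <- new("SegModel", config = arch, encoder = model@encoder,
                   head = best$head)
  attr(log, "trainNames") <- trainNames
  attr(log, "valNames") <- valNames
  new("SegCheckpoint", model = bestModel, bank = bank,
      epoch = as.integer(best$epoch), valIoU = unname(best$iou),
      valDice = unname(best$dice), log = log)
}

#' Save / load a checkpoint
#' @param ckpt A [SegCheckpoint-class].
#' @param path File path (RDS).
#' @return `path` invisibly, or the checkpoint.
#' @export
saveCheckpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
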