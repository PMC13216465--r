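## Evaluation harness: pixel confusion counts, IoU/Dice, dataset-level
## aggregation, the repeated group-sampling protocol, paired t-tests and
## the corner bias-patch preprocessing.

#' Pixel confusion counts between a prediction and the ground truth
#' @param pred,gt Binary matrices of equal shape.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
confusionCounts <- function(pred, gt) {
  assertMask(pred); assertMask(gt)
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch")
  c(tp = sum(pred == 1 & gt == 1),
    fp = sum(pred == 1 & gt == 0),
    fn = sum(pred == 0 & gt == 1))
}

#' IoU (Jaccard) and Dice from confusion counts
#'
#' `IoU = TP / (TP + FP + FN)` and `Dice = 2 TP / (2 TP + FP + FN)`.
#' When all three counts are zero (empty prediction vs empty truth) both
#' metrics are defined as 1 (perfect-agreement convention).
#'
#' @param counts Vector from [confusionCounts()].
#' @return Named vector `c(iou, dice)`.
#' @export
iouDice <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (tp + fp + fn == 0) return(c(iou = 1, dice = 1))
  c(iou = tp / (tp + fp + fn), dice = 2 * tp / (2 * tp + fp + fn))
}

#' Evaluate a directory of predictions against ground-truth masks
#'
#' Pairs files by name; per-image IoU and Dice plus their means and
#' population standard deviations (denominator n).
#'
#' @param predDir,gtDir Directories of 0/255 mask PNGs with matching names.
#' @return List with `perImage` (data.frame), `meanIoU`, `sdIoU`,
#'   `meanDice`, `sdDice`.
#' @export
evaluateDataset <- function(predDir, gtDir) {
  pf <- sort(dir(predDir, pattern = "\\.png$"))
  gf <- sort(dir(gtDir, pattern = "\\.png$"))
  common <- intersect(pf, gf)
  if (length(common) == 0)
    stop("no matching filenames between ", predDir, " and ", gtDir)
  miss <- c(setdiff(pf, gf), setdiff(gf, pf))
  if (length(miss) > 0)
    warning("unpaired files ignored: ", paste(miss, collapse = ", "))
  res <- t(vapply(common, function(f) {
    iouDice(confusionCounts(readMaskPNG(file.path(predDir, f)),
                            readMaskPNG(file.path(gtDir, f))))
  }, numeric(2)))
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  list(perImage = data.frame(file = common, iou = res[, "iou"],
                             dice = res[, "dice"], row.names = NULL),
       meanIoU = mean(res[, "iou"]), sdIoU = popSd(res[, "iou"]),
       meanDice = mean(res[, "dice"]), sdDice = popSd(res[, "dice"]))
}

#' Repeated group-sampling evaluation protocol
#'
#' Per trial, draws `groups` disjoint groups of `groupSize` images (without
#' replacement within the trial, seeded), computes the mean score per group
#' and the mean of the group means; reports the mean and (sample) standard
#' deviation of the trial means across `trials` trials.
#'
#' @param scores Per-image score vector.
#' @param groups Number of groups per trial (default 5).
#' @param groupSize Images per group (default 100).
#' @param trials Number of independent trials (default 50).
#' @param seed Sampling seed.
#' @return List with `trialMeans`, `mean`, `sd`.
#' @export
samplingEvaluation <- function(scores, groups = 5L, groupSize = 100L,
                               trials = 50L, seed = 0L) {
  n <- length(scores)
  if (groups * groupSize > n)
    stop("protocol infeasible: ", groups, " x ", groupSize,
         " exceeds the ", n, " available scores")
  trialMeans <- withSeed(seed, vapply(seq_len(trials), function(t) {
    idx <- sample.int(n, groups * groupSize)
    gm <- colMeans(matrix(scores[idx], groupSize, groups))
    mean(gm)
  }, numeric(1)))
  list(trialMeans = trialMeans, mean = mean(trialMeans),
       sd = sd(trialMeans))
}

#' Two-sided paired t-test on per-image scores
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, with
#' `n - 1` degrees of freedom (sample sd). Degenerate (zero-variance)
#' differences are an error: no p-value is fabricated.
#'
#' @param scoresA,scoresB Equal-length score vectors (n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
pairedTTest <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB)) stop("unequal lengths")
  n <- length(scoresA)
  if (n < 2) stop("need at least 2 pairs")
  d <- scoresA - scoresB
  if (sd(d) == 0)
    stop("degenerate paired differences (zero variance); t-test undefined")
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

#' Paint the bias-mitigation patch onto an image
#'
#' Adds a fixed-size black square to the lower-left corner, covering the
#' corner thumbnail whose colour otherwise leaks the image's class.
#' Idempotent; pixels outside the patch are untouched.
#'
#' @param image RGB raster.
#' @param patchSize Square side in pixels (default 64).
#' @return Patched raster.
#' @export
addBiasPatch <- function(image, patchSize = 64L) {
  assertImage(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < patchSize || w < patchSize)
    stop("image smaller than the bias patch")
  image[(h - patchSize + 1):h, 1:patchSize, ] <- 0
  image
}
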