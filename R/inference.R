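## Inference: probability maps from a trained checkpoint, thresholding, and
## the morphological refinement pipeline (closing, hole filling, largest
## connected component).

#' Predict a lesion probability map for an image
#'
#' Runs the encoder-memory comparison and the trained head in evaluation
#' mode; the probability map is resized back (bilinear) to the image's
#' native resolution.
#'
#' @param ckpt A [SegCheckpoint-class] (or a list with `model` and `bank`).
#' @param image RGB raster at any resolution.
#' @return Probability matrix in [0, 1] with the image's height/width.
#' @export
predictProb <- function(ckpt, image) {
  model <- if (is(ckpt, "SegCheckpoint")) ckpt@model else ckpt$model
  bank <- if (is(ckpt, "SegCheckpoint")) ckpt@bank else ckpt$bank
  sz <- model@config$inputSize
  native <- dim(image)[1:2]
  x <- if (all(native == sz)) image else resizeImage(image, sz, sz)
  prob <- segmentForward(model, x, bank)$prob
  if (!all(native == sz))
    prob <- pmin(pmax(ebResizeMatrix(prob, native[1], native[2]), 0), 1)
  prob
}

#' Threshold a probability map
#' @param prob Probability matrix in [0, 1].
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return Binary matrix (`prob >= threshold`).
#' @export
binarizeMask <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  (prob >= threshold) * 1
}

#' Morphological refinement of a binary prediction
#'
#' Closing with a 5x5 square structuring element, hole filling (4-connected
#' background flood fill from the border), and retention of only the
#' largest 8-connected foreground component (ties: first component in
#' raster scan order). Idempotent; an empty mask maps to an empty mask.
#'
#' @param mask Binary matrix.
#' @return Refined binary matrix with at most one component and no holes.
#' @export
postprocessMask <- function(mask) {
  assertMask(mask)
  if (sum(mask) == 0) return(mask * 0)
  closed <- EBImage::closing(EBImage::as.Image(t(mask)),
                             EBImage::makeBrush(5, "box"))
  m <- t(EBImage::imageData(closed))
  m <- fillholes_cpp((m >= 0.5) * 1)
  lab <- label8_cpp(m)
  if (max(lab) == 0) return(m * 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # which.max takes the first maximum
  (lab == keep) * 1
}

#' Segment a directory of images with a trained checkpoint
#'
#' @param ckpt A [SegCheckpoint-class].
#' @param imageDir Directory of input PNGs.
#' @param outDir Output directory for 0/255 mask PNGs.
#' @param threshold Binarization threshold.
#' @param postprocess Apply [postprocessMask()].
#' @return Invisibly, the vector of written files.
#' @export
inferDirectory <- function(ckpt, imageDir, outDir, threshold = 0.5,
                           postprocess = TRUE) {
  files <- sort(dir(imageDir, pattern = "\\.png$"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (f in files) {
    prob <- predictProb(ckpt, readImageRGB(file.path(imageDir, f)))
    m <- binarizeMask(prob, threshold)
    if (postprocess) m <- postprocessMask(m)
    writeMaskPNG(m, file.path(outDir, f))
  }
  invisible(files)
}
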