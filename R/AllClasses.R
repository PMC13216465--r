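#' @include utils.R
NULL

#' Set of pre-generated polyp template masks
#'
#' An ordered, fixed-size collection of binary 512x512 (by default) lesion
#' footprint rasters, each rasterized from a fresh random polar-harmonic
#' contour. Reproducible from its seed.
#'
#' @slot masks List of binary matrices.
#' @slot seed Integer seed the set was generated from.
#' @slot grid Side length of the raster grid in pixels.
#' @export
setClass("MaskTemplateSet",
  representation(masks = "list", seed = "integer", grid = "integer"),
  validity = function(object) {
    if (length(object@masks) < 1L) return("empty template set")
    if (any(!vapply(object@masks, function(m) sum(m) > 0, logical(1))))
      return("all templates must have at least one foreground pixel")
    TRUE
  })

#' @describeIn MaskTemplateSet Number of templates.
#' @param x A `MaskTemplateSet`.
#' @export
setMethod("length", "MaskTemplateSet", function(x) length(x@masks))

#' @describeIn MaskTemplateSet Extract one template mask (binary matrix).
#' @param i Template index.
#' @export
setMethod("[[", "MaskTemplateSet", function(x, i) x@masks[[i]])

setMethod("show", "MaskTemplateSet", function(object) {
  cat("MaskTemplateSet of", length(object@masks), "templates on a",
      object@grid, "x", object@grid, "grid (seed", object@seed, ")\n")
})

#' Accessor: template masks as a list
#' @param x A `MaskTemplateSet`.
#' @return List of binary matrices.
#' @export
templateMasks <- function(x) x@masks

#' One synthetic training pair produced by the lesion simulator
#'
#' @slot image Composite RGB raster (H x W x 3, [0, 255]).
#' @slot mask Aligned binary ground-truth mask.
#' @slot mode Synthesis mode: `"patch"`, `"texture"` or `"hybrid"`.
#' @slot alpha Hybrid interpolation factor (`NA` for non-hybrid modes).
#' @slot seed Master seed the sample was generated from.
#' @export
setClass("SyntheticSample",
  representation(image = "array", mask = "matrix", mode = "character",
                 alpha = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("patch", "texture", "hybrid"))
      return("mode must be patch, texture or hybrid")
    if (sum(object@mask) < 1) return("mask must be nonempty")
    if (!all(dim(object@image)[1:2] == dim(object@mask)))
      return("image and mask sizes differ")
    TRUE
  })

setMethod("show", "SyntheticSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticSample %dx%d, mode %s, lesion %d px (seed %d)\n",
              d[1], d[2], object@mode, sum(object@mask), object@seed))
})

#' Accessors for SyntheticSample slots
#' @param x A `SyntheticSample`.
#' @return The image array, mask matrix, or mode string.
#' @export
sampleImage <- function(x) x@image

#' @rdname sampleImage
#' @export
sampleMask <- function(x) x@mask

#' @rdname sampleImage
#' @export
sampleMode <- function(x) x@mode

#' Fixed bank of normal-image feature prototypes
#'
#' Multi-scale feature embeddings of N polyp-free images, encoded once and
#' frozen. Each element of `pyramids` is a per-image list of three feature
#' arrays (finest to coarsest scale).
#'
#' @slot pyramids List of feature pyramids (one per stored image).
#' @slot indices Integer indices of the images selected from the pool.
#' @slot inputSize Side length the images were encoded at.
#' @export
setClass("MemoryBank",
  representation(pyramids = "list", indices = "integer",
                 inputSize = "integer"),
  validity = function(object) {
    if (length(object@pyramids) < 1L) return("memory bank must hold N >= 1")
    TRUE
  })

#' @describeIn MemoryBank Number of stored prototypes.
#' @param x A `MemoryBank`.
#' @export
setMethod("length", "MemoryBank", function(x) length(x@pyramids))

setMethod("show", "MemoryBank", function(object) {
  cat("MemoryBank of", length(object@pyramids),
      "normal prototypes encoded at", object@inputSize, "px\n")
})

#' Memory-augmented segmentation network
#'
#' Holds the frozen multi-scale encoder, the trainable fusion/attention/
#' decoder head, and the architecture configuration.
#'
#' @slot config Architecture configuration list (see [modelConfig()]).
#' @slot encoder Named list of frozen encoder parameter arrays.
#' @slot head Named list of trainable head parameter arrays.
#' @export
setClass("SegModel",
  representation(config = "list", encoder = "list", head = "list"))

setMethod("show", "SegModel", function(object) {
  p <- countParameters(object)
  cat(sprintf(
    "SegModel: %.2fM parameters (%.2fM trainable, %.2fM frozen encoder)\n",
    p["total"] / 1e6, p["trainable"] / 1e6,
    (p["total"] - p["trainable"]) / 1e6))
})

#' Trained model checkpoint
#'
#' @slot model The [SegModel-class] at the selected epoch.
#' @slot bank The [MemoryBank-class] used for training and inference.
#' @slot epoch Epoch index of the retained checkpoint.
#' @slot valIoU,valDice Validation metrics at that epoch.
#' @slot log Per-epoch training log (data.frame).
#' @export
setClass("SegCheckpoint",
  representation(model = "SegModel", bank = "MemoryBank", epoch = "integer",
                 valIoU = "numeric", valDice = "numeric", log = "data.frame"))

setMethod("show", "SegCheckpoint", function(object) {
  cat(sprintf(
    "SegCheckpoint at epoch %d: val IoU %.3f, val Dice %.3f (mean %.3f)\n",
    object@epoch, object@valIoU, object@valDice,
    (object@valIoU + object@valDice) / 2))
})

#' Mean segmentation score of a checkpoint
#' @param x A `SegCheckpoint`.
#' @return `(IoU + Dice) / 2` on the validation set.
#' @export
meanScore <- function(x) (x@valIoU + x@valDice) / 2
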