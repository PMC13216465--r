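## Synthetic polyp compositing: pick a template mask, transform and place it
## into the valid region of a normal frame, then fill it with one of three
## content strategies (patch / texture / hybrid), each mimicking a clinical
## lesion phenotype class, with soft shadow blending at the rim.

#' Default photometric/geometric transformation table
#'
#' One row per operation, applied independently with its probability and a
#' parameter drawn uniformly from its range, in row order: horizontal and
#' vertical flips, rotation, anisotropic x-scaling, intensity multiply,
#' gamma contrast, Gaussian blur and hue/saturation shift.
#'
#' @return data.frame with columns `name`, `lo`, `hi`, `prob`.
#' @export
defaultTransformConfig <- function() {
  data.frame(
    name = c("hflip", "vflip", "rotate", "aniso_x", "intensity", "gamma",
             "blur", "hue_sat"),
    lo   = c(NA, NA, -90, 0.65, 1.5, 0.5, 5, -10),
    hi   = c(NA, NA,  90, 1.00, 2.0, 1.5, 5,  10),
    prob = c(0.5, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

#' Draw synthesis modes
#'
#' Categorical draw over the three content strategies with the default
#' weights 0.4 (patch), 0.4 (texture), 0.2 (hybrid).
#'
#' @param n Number of draws.
#' @param weights Named or positional weights for (patch, texture, hybrid);
#'   must sum to 1.
#' @param seed Optional seed; if `NULL`, draws from the current stream.
#' @return Character vector of modes.
#' @export
selectMode <- function(n = 1L, weights = c(patch = 0.4, texture = 0.4,
                                           hybrid = 0.2), seed = NULL) {
  if (abs(sum(weights) - 1) > 1e-9) stop("mode weights must sum to 1")
  modes <- c("patch", "texture", "hybrid")
  f <- function() sample(modes, n, replace = TRUE, prob = weights)
  if (is.null(seed)) f() else withSeed(seed, f())
}

## affine helpers for the geometric rows (about the image centre,
## replicate borders)
warpImageAffine <- function(img, A) {
  Ainv <- solve(A)
  ctr <- (dim(img)[1:2] + 1) / 2
  out <- img
  empty <- matrix(0, 0, 0)
  for (c in 1:3)
    out[, , c] <- warp_cpp(img[, , c], Ainv, 0, 0, ctr[2], ctr[1],
                           empty, empty, 1L)
  out
}

#' Apply the photometric/geometric transformation table to an image
#'
#' Each configured operation fires independently with its probability; its
#' parameter is drawn uniformly from its range. Output is clipped to
#' [0, 255]. Deterministic for a fixed seed.
#'
#' @param img RGB raster ([0, 255]).
#' @param seed Integer seed.
#' @param config Transformation table (see [defaultTransformConfig()]).
#' @return Transformed raster.
#' @export
applyPhotometricGeometric <- function(img, seed = 0L,
                                      config = defaultTransformConfig()) {
  assertImage(img)
  withSeed(seed, {
    for (i in seq_len(nrow(config))) {
      row <- config[i, ]
      if (runif(1) > row$prob) next
      par <- if (is.na(row$lo)) NA else runif(1, row$lo, row$hi)
      img <- switch(row$name,
        hflip = img[, rev(seq_len(dim(img)[2])), , drop = FALSE],
        vflip = img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
        rotate = {
          th <- par * pi / 180
          warpImageAffine(img, matrix(c(cos(th), sin(th),
                                        -sin(th), cos(th)), 2))
        },
        aniso_x = warpImageAffine(img, diag(c(par, 1))),
        intensity = clamp255(img * par),
        gamma = 255 * (clamp255(img) / 255)^par,
        blur = blurImage(img, par),
        hue_sat = {
          d <- par
          hsvm <- rgb2hsvImage(img)
          hsvm[1, ] <- ((hsvm[1, ] * 360 + d) %% 360) / 360
          hsvm[2, ] <- pmin(pmax(hsvm[2, ] + d / 255, 0), 1)
          hsvImage2rgb(hsvm, dim(img)[1:2])
        },
        stop("unknown transform: ", row$name))
    }
    clamp255(img)
  })
}

#' Composite lesion content into a base image with a soft shadow
#'
#' The mask is Gaussian-blurred (truncated kernel) and peak-normalised to a
#' weight field B. The base is darkened by `(1 - lambda * B)` - a soft
#' shadow concentrated along the lesion contour - and the content is then
#' overlaid inside the mask with B-weighted feathering at the rim. Pixels
#' with exactly zero blurred-mask weight are bit-identical to the base.
#'
#' @param base Base RGB raster.
#' @param content Lesion content raster (same shape).
#' @param mask Binary lesion mask.
#' @param sigma Shadow blur scale in pixels.
#' @param lambda Shadow darkening strength in [0, 1].
#' @return Composited raster.
#' @export
shadowBlend <- function(base, content, mask, sigma = 7, lambda = 0.3) {
  assertImage(base); assertImage(content); assertMask(mask)
  if (!all(dim(base) == dim(content)) || !all(dim(base)[1:2] == dim(mask)))
    stop("shape mismatch")
  B <- gaussianBlur(mask, sigma, border = "zero")
  mB <- max(B)
  if (mB == 0) return(base)
  Bn <- B / mB
  w <- mask * Bn
  out <- base
  for (c in 1:3) {
    shadowed <- base[, , c] * (1 - lambda * Bn)
    out[, , c] <- shadowed + w * (content[, , c] - shadowed)
  }
  out
}

## centre-crop or tile a texture to the target size
tileTexture <- function(tex, h, w) {
  th <- dim(tex)[1]; tw <- dim(tex)[2]
  ri <- ((seq_len(h) - 1) %% th) + 1
  ci <- ((seq_len(w) - 1) %% tw) + 1
  if (th >= h) ri <- floor((th - h) / 2) + seq_len(h)
  if (tw >= w) ci <- floor((tw - w) / 2) + seq_len(w)
  tex[ri, ci, , drop = FALSE]
}

#' Patch-based lesion synthesis
#'
#' Emulates homogeneous, mucosa-coloured lesions: the content is the base
#' image itself after the photometric/geometric transform table, overlaid
#' through the mask with shadow blending.
#'
#' @param I Base RGB raster.
#' @param M Placed binary lesion mask.
#' @param seed Master seed for the sample.
#' @param config Transformation table.
#' @param shadowSigma,shadowLambda Shadow parameters.
#' @return A [SyntheticSample-class] with mode `"patch"`.
#' @export
patchSynthesis <- function(I, M, seed = 0L,
                           config = defaultTransformConfig(),
                           shadowSigma = 7, shadowLambda = 0.3) {
  Ip <- applyPhotometricGeometric(I, deriveSeed(seed, "transformI"), config)
  O <- shadowBlend(I, Ip, M, shadowSigma, shadowLambda)
  new("SyntheticSample", image = O, mask = unname(M) * 1, mode = "patch",
      alpha = NA_real_, seed = as.integer(seed))
}

#' Texture-based lesion synthesis
#'
#' Emulates dark, heterogeneous lesions: an external texture is colour
#' matched to the base image (iterative distribution transfer + structure
#' restoration), transformed, and composited through the mask.
#'
#' @inheritParams patchSynthesis
#' @param T_ External texture raster (tiled/cropped to the image size).
#' @param nIter Colour-transfer iterations.
#' @return A [SyntheticSample-class] with mode `"texture"`.
#' @export
textureSynthesis <- function(I, T_, M, seed = 0L,
                             config = defaultTransformConfig(),
                             shadowSigma = 7, shadowLambda = 0.3,
                             nIter = 10L) {
  Tt <- tileTexture(T_, dim(I)[1], dim(I)[2])
  Tc <- adaptTextureColor(Tt, I, nIter, deriveSeed(seed, "idt"))
  Tp <- applyPhotometricGeometric(Tc, deriveSeed(seed, "transformT"), config)
  O <- shadowBlend(I, Tp, M, shadowSigma, shadowLambda)
  new("SyntheticSample", image = O, mask = unname(M) * 1, mode = "texture",
      alpha = NA_real_, seed = as.integer(seed))
}

#' Hybrid fusion lesion synthesis
#'
#' Fills the mask with a convex combination of the patch content and the
#' colour-matched texture content,
#' `(1 - alpha) * I' + alpha * Tc'` with `alpha ~ U(0.3, 0.7)`, then
#' composites with the same shadow blending. `alpha = 0` and `alpha = 1`
#' reduce exactly to the patch and texture modes under shared seeds.
#'
#' @inheritParams textureSynthesis
#' @param alpha Optional forced interpolation factor in [0, 1].
#' @return A [SyntheticSample-class] with mode `"hybrid"`.
#' @export
hybridSynthesis <- function(I, T_, M, seed = 0L,
                            config = defaultTransformConfig(),
                            shadowSigma = 7, shadowLambda = 0.3,
                            nIter = 10L, alpha = NULL) {
  if (is.null(alpha))
    alpha <- withSeed(deriveSeed(seed, "alpha"), runif(1, 0.3, 0.7))
  Ip <- applyPhotometricGeometric(I, deriveSeed(seed, "transformI"), config)
  Tt <- tileTexture(T_, dim(I)[1], dim(I)[2])
  Tc <- adaptTextureColor(Tt, I, nIter, deriveSeed(seed, "idt"))
  Tp <- applyPhotometricGeometric(Tc, deriveSeed(seed, "transformT"), config)
  content <- (1 - alpha) * Ip + alpha * Tp
  O <- shadowBlend(I, content, M, shadowSigma, shadowLambda)
  new("SyntheticSample", image = O, mask = unname(M) * 1, mode = "hybrid",
      alpha = alpha, seed = as.integer(seed))
}

#' Generate one synthetic training pair from a normal image
#'
#' Full simulator pipeline: sample a template, transform it, restrict it to
#' the image's valid mucosal region, draw a synthesis mode (40/40/20), and
#' dispatch to the matching content strategy. One master seed spawns
#' independent substreams for each stage, so every component is
#' individually reproducible.
#'
#' @param I Normal RGB raster.
#' @param templates A [MaskTemplateSet-class].
#' @param textures List of texture rasters.
#' @param seed Master seed.
#' @param config Transformation table.
#' @param modeWeights Synthesis-mode weights (sum to 1).
#' @param validRegion Optional precomputed valid-region mask for `I`.
#' @param ... Passed to the synthesis functions (shadow, nIter).
#' @return A [SyntheticSample-class].
#' @export
generateSample <- function(I, templates, textures, seed = 0L,
                           config = defaultTransformConfig(),
                           modeWeights = c(patch = 0.4, texture = 0.4,
                                           hybrid = 0.2),
                           validRegion = NULL, ...) {
  stopifnot(is(templates, "MaskTemplateSet"), length(textures) >= 1)
  idx <- withSeed(deriveSeed(seed, "pick"),
                  sample.int(length(templates), 1))
  mt <- transformMask(templates[[idx]], targetSize = dim(I)[1],
                      seed = deriveSeed(seed, "masktrans"))
  mo <- if (is.null(validRegion)) computeValidRegion(I) else validRegion
  M <- placeMask((mt >= 0.5) * 1, mo, seed = deriveSeed(seed, "place"),
                 context = paste0("sample seed ", seed))
  mode <- selectMode(1, modeWeights, seed = deriveSeed(seed, "mode"))
  tex <- textures[[withSeed(deriveSeed(seed, "texsel"),
                            sample.int(length(textures), 1))]]
  out <- switch(mode,
    patch = patchSynthesis(I, M, seed, config, ...),
    texture = textureSynthesis(I, tex, M, seed, config, ...),
    hybrid = hybridSynthesis(I, tex, M, seed, config, ...))
  out
}
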