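## Iterative distribution transfer: recolour a texture so its 3D colour
## distribution matches a reference image while keeping the texture's
## structure. Repeated 1D quantile matching along rotated orthonormal axes
## progressively aligns the full joint distribution; a final restoration
## step reinstates the original high-frequency structure.

#' Monotone 1D distribution matching
#'
#' Maps source samples so their empirical quantiles equal the target's,
#' with linear interpolation between order statistics; ties are broken by
#' stable sort.
#'
#' @param source,target Numeric sample vectors (nonempty).
#' @return Transformed source samples (same length/order as `source`).
#' @export
matchCdf1d <- function(source, target) {
  n <- length(source); m <- length(target)
  if (n == 0 || m == 0) stop("matchCdf1d: empty input")
  ts <- sort(target)
  if (m == 1) return(rep(ts, n))
  probsT <- (seq_len(m) - 0.5) / m
  probsS <- (seq_len(n) - 0.5) / n
  mapped <- stats::approx(probsT, ts, xout = probsS, rule = 2)$y
  out <- numeric(n)
  out[order(source)] <- mapped
  out
}

#' Convert an RGB raster to a colour point cloud
#' @param img H x W x 3 array.
#' @return n x 3 matrix with an `origin` attribute holding `c(H, W)`.
#' @export
imageToCloud <- function(img) {
  assertImage(img)
  d <- dim(img)
  structure(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                  as.vector(img[, , 3])),
            origin = d[1:2])
}

#' Reshape a colour cloud back to an image
#' @param cloud n x 3 matrix with an `origin` attribute.
#' @return H x W x 3 array.
#' @export
cloudToImage <- function(cloud) {
  o <- attr(cloud, "origin")
  array(c(cloud[, 1], cloud[, 2], cloud[, 3]), dim = c(o, 3L))
}

#' One distribution-transfer step along an orthonormal basis
#'
#' Projects both clouds on each of the three axes, matches the 1D
#' marginals, and rotates the result back. After the step the source's
#' marginal along every basis axis equals the target's (at source ranks,
#' up to interpolation).
#'
#' @param source,target n x 3 colour clouds.
#' @param basis 3 x 3 matrix whose columns are orthonormal axes.
#' @return Transformed source cloud (attributes preserved).
#' @export
idtStep <- function(source, target, basis = diag(3)) {
  if (max(abs(crossprod(basis) - diag(3))) > 1e-6)
    stop("basis is not orthonormal")
  ps <- source %*% basis
  pt <- target %*% basis
  for (j in 1:3) ps[, j] <- matchCdf1d(ps[, j], pt[, j])
  out <- ps %*% t(basis)
  attributes(out) <- attributes(source)[c("dim", "origin")]
  out
}

randomOrthonormalBasis <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

#' Iterative colour distribution transfer
#'
#' Repeats [idtStep()] with a fresh random orthonormal basis per iteration
#' (the first iteration uses the RGB identity basis), progressively
#' aligning the texture's colour distribution with the reference's.
#'
#' @param texture RGB raster to be recoloured.
#' @param reference RGB raster providing the target colour distribution.
#' @param nIter Number of iterations (>= 1; mismatch plateaus by ~10).
#' @param seed Seed for the rotation stream.
#' @return Recoloured raster, clipped to [0, 255].
#' @export
iterativeDistributionTransfer <- function(texture, reference, nIter = 10L,
                                          seed = 0L) {
  if (nIter < 1) stop("nIter must be >= 1")
  src <- imageToCloud(texture)
  tgt <- imageToCloud(reference)
  withSeed(seed, {
    for (it in seq_len(nIter)) {
      basis <- if (it == 1L) diag(3) else randomOrthonormalBasis()
      src <- idtStep(src, tgt, basis)
    }
  })
  src[] <- pmin(pmax(src, 0), 255)
  cloudToImage(src)
}

#' Restore texture structure after recolouring
#'
#' Splits both rasters into Gaussian low/high-frequency components and
#' combines the recoloured low-pass with the original's high-pass per
#' channel: the colour comes from the recoloured image, the structural
#' detail from the original.
#'
#' @param original Original texture raster.
#' @param recolored Recoloured raster (same shape).
#' @param sigma Gaussian split scale in pixels.
#' @return Restored raster, clipped to [0, 255].
#' @export
textureRestoration <- function(original, recolored, sigma = 2) {
  assertImage(original); assertImage(recolored)
  if (!all(dim(original) == dim(recolored))) stop("shape mismatch")
  out <- original
  for (c in 1:3) {
    lowR <- gaussblur_cpp(recolored[, , c], sigma, 1L)
    lowO <- gaussblur_cpp(original[, , c], sigma, 1L)
    out[, , c] <- lowR + (original[, , c] - lowO)
  }
  clamp255(out)
}

#' Full colour adaptation of a texture to a reference image
#'
#' [iterativeDistributionTransfer()] followed by [textureRestoration()].
#'
#' @inheritParams iterativeDistributionTransfer
#' @return Colour-matched texture raster.
#' @export
adaptTextureColor <- function(texture, reference, nIter = 10L, seed = 0L) {
  recol <- iterativeDistributionTransfer(texture, reference, nIter, seed)
  textureRestoration(texture, recol)
}
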