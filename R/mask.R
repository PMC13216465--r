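## Lesion footprint generation: polar-harmonic contours rasterized to binary
## templates, and the transform/placement pipeline that turns a template into
## an anatomically valid mask for a specific target image.

#' Sample a random polar-harmonic contour specification
#'
#' The lesion boundary is a unit circle perturbed by `n` sinusoidal
#' harmonics: phases are uniform on `[0, 2*pi)`, per-harmonic scales uniform
#' on `[0, 1]`, and amplitudes decay quadratically with frequency
#' (`1/i^2`, Brownian-noise spectrum), which yields smooth organic outlines.
#'
#' @param n Number of harmonics (default 1000).
#' @param sharedXi If `TRUE`, a single scale factor is shared by all
#'   harmonics instead of independent per-harmonic scales.
#' @return A `ContourSpec` list with fields `n`, `phi`, `xi`, `omega`.
#'   Draws from the current RNG stream; seed outside.
#' @export
sampleContour <- function(n = 1000L, sharedXi = FALSE) {
  if (n < 1) stop("n must be >= 1")
  phi <- runif(n, 0, 2 * pi)
  xi <- if (sharedXi) rep(runif(1), n) else runif(n)
  structure(list(n = as.integer(n), phi = phi, xi = xi,
                 omega = 1 / seq_len(n)^2),
            class = "ContourSpec")
}

#' Evaluate the contour radius at given angles
#'
#' `r(theta) = 1 + sum_i xi_i * omega_i * sin(i * theta + phi_i)`; the
#' deviation from 1 is bounded by `sum_i xi_i * omega_i`.
#'
#' @param spec A `ContourSpec`.
#' @param theta Angles in radians (vectorised).
#' @return Radii (dimensionless).
#' @export
evaluateRadius <- function(spec, theta) {
  stopifnot(inherits(spec, "ContourSpec"))
  amp <- spec$xi * spec$omega
  # rows: harmonics, cols: angles
  ang <- outer(seq_len(spec$n), theta) + spec$phi
  1 + as.vector(crossprod(sin(ang), amp))
}

degenerateContourCondition <- function() {
  structure(class = c("polypseg_degenerate_contour", "error", "condition"),
            list(message = "contour has nonpositive radius; resample",
                 call = NULL))
}

#' Rasterize a contour specification to a binary template mask
#'
#' The contour is discretized at `kPoints` equally spaced angles, densified
#' by closed periodic cubic splines on the Cartesian boundary coordinates
#' (factor `upsample`), rescaled (aspect preserved) so its larger
#' bounding-box side spans 90% of the grid, centred, and filled by scanline
#' polygon rasterization.
#'
#' @param spec A `ContourSpec`.
#' @param kPoints Number of contour samples (default 50).
#' @param upsample Spline densification factor (default 10).
#' @param grid Raster side length in pixels (default 512).
#' @return Binary `grid` x `grid` matrix; the boundary polygon is attached
#'   as attributes `bx`, `by`. A contour with nonpositive radius anywhere
#'   raises a condition of class `polypseg_degenerate_contour`.
#' @export
rasterizeTemplate <- function(spec, kPoints = 50L, upsample = 10L,
                              grid = 512L) {
  if (kPoints < 3) stop("kPoints must be >= 3")
  thetaK <- seq(0, 2 * pi, length.out = kPoints + 1)
  r <- evaluateRadius(spec, thetaK)
  if (any(r <= 0)) stop(degenerateContourCondition())
  x <- r * cos(thetaK)
  y <- r * sin(thetaK)
  x[kPoints + 1] <- x[1]; y[kPoints + 1] <- y[1]  # close exactly
  m <- kPoints * upsample
  tOut <- seq(0, 2 * pi, length.out = m + 1)[seq_len(m)]
  bx <- spline(thetaK, x, method = "periodic", xout = tOut)$y
  by <- spline(thetaK, y, method = "periodic", xout = tOut)$y
  rngx <- range(bx); rngy <- range(by)
  scl <- 0.9 * grid / max(diff(rngx), diff(rngy))
  px <- (bx - mean(rngx)) * scl + (grid + 1) / 2
  py <- (by - mean(rngy)) * scl + (grid + 1) / 2
  out <- polyfill_cpp(px, py, grid, grid)
  if (sum(out) < 1) stop(degenerateContourCondition())
  attr(out, "bx") <- px
  attr(out, "by") <- py
  out
}

#' Build the template mask dataset
#'
#' Pre-generates `count` binary templates, each from a freshly sampled
#' contour (degenerate contours are resampled). Reproducible from the seed.
#'
#' @param count Number of templates (the reference dataset uses 1000).
#' @param seed Master seed.
#' @param n Harmonics per contour.
#' @param grid Raster side length.
#' @param sharedXi Passed to [sampleContour()].
#' @return A [MaskTemplateSet-class].
#' @export
buildTemplateSet <- function(count = 1000L, seed = 0L, n = 1000L,
                             grid = 512L, sharedXi = FALSE) {
  if (count < 1) stop("count must be >= 1")
  masks <- vector("list", count)
  for (i in seq_len(count)) {
    masks[[i]] <- withSeed(deriveSeed(seed, "template", i), {
      rep <- 0L
      repeat {
        m <- tryCatch(
          rasterizeTemplate(sampleContour(n, sharedXi), grid = grid),
          polypseg_degenerate_contour = function(e) NULL)
        if (!is.null(m)) break
        rep <- rep + 1L
        if (rep > 20L) stop("could not sample a valid contour")
      }
      attr(m, "bx") <- NULL; attr(m, "by") <- NULL
      m
    })
  }
  new("MaskTemplateSet", masks = masks, seed = as.integer(seed),
      grid = as.integer(grid))
}

#' Persist a template set as 1-bit PNGs plus a YAML manifest
#' @param tset A [MaskTemplateSet-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveTemplateSet <- function(tset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(tset))
  for (i in seq_along(tset@masks)) {
    files[i] <- sprintf("template_%04d.png", i)
    writeMaskPNG(tset@masks[[i]], file.path(dir, files[i]))
  }
  yaml::write_yaml(list(seed = tset@seed, grid = tset@grid, count =
                          length(tset@masks), files = files),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a template set saved by [saveTemplateSet()]
#' @param dir Directory holding the PNGs and manifest.
#' @return A [MaskTemplateSet-class].
#' @export
loadTemplateSet <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  masks <- lapply(man$files, function(f) readMaskPNG(file.path(dir, f)))
  new("MaskTemplateSet", masks = masks, seed = as.integer(man$seed),
      grid = as.integer(man$grid))
}

## coarse random displacement field for elastic deformation:
## 8x8 control grid, bilinear upscaling, Gaussian smoothing, peak
## displacement capped at 5% of the image size.
elasticField <- function(size, maxFrac = 0.05, controls = 8L) {
  f <- function() {
    g <- matrix(runif(controls^2, -1, 1), controls)
    d <- ebResizeMatrix(g, size, size)
    d <- gaussianBlur(d, max(1, size / 32), border = "replicate")
    pk <- max(abs(d))
    if (pk > 0) d <- d / pk * maxFrac * size
    d
  }
  list(dx = f(), dy = f())
}

## warp a template onto the target grid (see warp_grid_cpp); elastic
## displacements are drawn on the target grid and rescaled to template
## coordinates
warpToGrid <- function(template, targetSize, Ainv, tr, ctrO, ctrT, ef) {
  q <- nrow(template) / targetSize
  empty <- matrix(0, 0, 0)
  if (is.null(ef))
    warp_grid_cpp(template, targetSize, targetSize, Ainv, tr[1], tr[2],
                  ctrO, ctrO, ctrT, ctrT, empty, empty, 0)
  else
    warp_grid_cpp(template, targetSize, targetSize, Ainv, tr[1], tr[2],
                  ctrO, ctrO, ctrT, ctrT, ef$dx, ef$dy, q)
}

#' Transform a template mask into a placed lesion footprint
#'
#' Pipeline: downscale the template to 60% of its extent, rotate randomly,
#' translate randomly (keeping the lesion fully inside the frame), apply an
#' elastic deformation, scale globally by `s ~ U(0.2, 0.9)`, and resample
#' onto the target grid. All transforms are realised as one inverse-mapped
#' warp, so the forced identity parameters reproduce the template exactly.
#'
#' @param template Binary template matrix.
#' @param targetSize Side length of the output grid.
#' @param seed Integer seed for the random draws (ignored when all
#'   parameters are forced via `params`).
#' @param params Optional list forcing `rotate` (degrees), `translate`
#'   (c(tx, ty) pixels), `elastic` (logical), `scale`, `downscale`; unset
#'   entries are drawn randomly.
#' @param maxRetries Retries when a transform empties the mask.
#' @return Binary `targetSize` x `targetSize` matrix with attributes
#'   `scale`, `rotate`, `translate`.
#' @export
transformMask <- function(template, targetSize = 512L, seed = 0L,
                          params = list(), maxRetries = 10L) {
  assertMask(template)
  sz <- nrow(template)
  draw <- function(name, expr) {
    if (!is.null(params[[name]])) params[[name]] else expr
  }
  ## the affine (downscale, rotate, scale, translate), the elastic field
  ## and the final resampling onto the target grid are realised as one
  ## inverse-mapped warp evaluated directly on the target grid
  q <- sz / targetSize
  fg <- which(template == 1, arr.ind = TRUE)
  bb <- cbind(range(fg[, 2]), range(fg[, 1]))  # x, y in template coords
  withSeed(seed, {
    for (att in seq_len(maxRetries)) {
      rot <- draw("rotate", runif(1, -180, 180))
      dsc <- draw("downscale", 0.6)
      s <- draw("scale", runif(1, 0.2, 0.9))
      useEl <- draw("elastic", TRUE)
      total <- dsc * s
      th <- rot * pi / 180
      ctrT <- (sz + 1) / 2
      ctrO <- (targetSize + 1) / 2
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      ## conservative bounding box of the transformed shape (rotated
      ## template bbox corners), in target-grid coordinates
      corners <- rbind(c(bb[1, 1], bb[1, 2]), c(bb[1, 1], bb[2, 2]),
                       c(bb[2, 1], bb[1, 2]), c(bb[2, 1], bb[2, 2]))
      fwd <- t(total * R %*% (t(corners) - ctrT)) / q + ctrO
      pad <- if (useEl) 0.05 * targetSize else 0
      loTx <- -(min(fwd[, 1]) - 1) + pad; hiTx <- targetSize - max(fwd[, 1]) - pad
      loTy <- -(min(fwd[, 2]) - 1) + pad; hiTy <- targetSize - max(fwd[, 2]) - pad
      tr <- draw("translate",
                 c(if (hiTx > loTx) runif(1, loTx, hiTx) else 0,
                   if (hiTy > loTy) runif(1, loTy, hiTy) else 0))
      ## inverse map: target px -> centred -> untranslate -> unrotate/scale
      ## -> template coords; composed as warp_cpp's affine about ctrO with
      ## a coordinate rescale baked in via Ainv and centre shift
      Ainv <- (q / total) * t(R)
      ef <- if (useEl) elasticField(targetSize) else NULL
      out <- warpToGrid(template, targetSize, Ainv, tr, ctrO, ctrT, ef)
      out <- (out >= 0.5) * 1
      if (sum(out) > 0) {
        attr(out, "scale") <- s
        attr(out, "rotate") <- rot
        attr(out, "translate") <- tr
        return(out)
      }
    }
    stop("transformMask: foreground lost after ", maxRetries, " attempts")
  })
}

#' Compute the anatomically valid placement region of an image
#'
#' Separates mucosal tissue from near-black borders, overlays and corner
#' thumbnails by intensity thresholding: an Otsu threshold on the luma,
#' clamped to the [20, 50] guard band (a hard floor for black overlays and
#' a cap so bright tissue is never split), followed by a 3x3 morphological
#' opening to drop speckle.
#'
#' @param image RGB raster (H x W x 3, [0, 255]).
#' @return Binary matrix of valid placement pixels; a warning is emitted
#'   when the region is empty.
#' @export
computeValidRegion <- function(image) {
  assertImage(image)
  lum <- luma(image)
  thr <- tryCatch(
    255 * EBImage::otsu(EBImage::as.Image(t(lum) / 255)),
    error = function(e) 50)
  thr <- min(max(thr, 20), 50)
  valid <- (lum >= thr) * 1
  if (sum(valid) > 0)
    valid <- morph3x3(valid, "open")
  if (sum(valid) == 0)
    warning("valid region is empty (fully dark image?)")
  valid
}

## 3x3 binary erosion/dilation with replicate border (so a fully-bright
## image stays fully valid), and opening = erode then dilate.
morph3x3 <- function(m, op = c("open", "erode", "dilate")) {
  op <- match.arg(op)
  shift <- function(x, dr, dc) {
    H <- nrow(x); W <- ncol(x)
    ri <- pmin(pmax(seq_len(H) + dr, 1), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1), W)
    x[ri, ci, drop = FALSE]
  }
  agg <- function(x, f) {
    acc <- x
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- f(acc, shift(x, dr, dc))
    }
    acc
  }
  if (op == "erode") return(agg(m, pmin))
  if (op == "dilate") return(agg(m, pmax))
  agg(agg(m, pmin), pmax)
}

#' Intersect a transformed lesion mask with the valid region
#'
#' The final mask is the element-wise product of the valid region and the
#' transformed template, which confines placement to consistent anatomy.
#' If the intersection is empty or loses more than half of the lesion
#' area, placement is re-drawn by translating the lesion within the frame
#' (bounded retries).
#'
#' @param mt Transformed lesion mask (binary, same size as `mo`).
#' @param mo Valid-region mask (binary).
#' @param seed Seed for placement re-draws.
#' @param maxRetries Retry bound.
#' @param context Image name used in the error message.
#' @return Binary mask `mo * mt` (possibly after re-translation).
#' @export
placeMask <- function(mt, mo, seed = 0L, maxRetries = 10L,
                      context = "image") {
  assertMask(mt); assertMask(mo)
  if (!all(dim(mt) == dim(mo))) stop("mask sizes differ")
  ok <- function(m, area) sum(m) > 0 && sum(m) >= 0.5 * area
  M <- mo * mt
  if (ok(M, sum(mt))) return(M)
  H <- nrow(mt); W <- ncol(mt)
  withSeed(seed, {
    for (i in seq_len(maxRetries)) {
      fg <- which(mt == 1, arr.ind = TRUE)
      rr <- range(fg[, 1]); cc <- range(fg[, 2])
      dy <- sample.int(H - (rr[2] - rr[1]), 1) - rr[1]
      dx <- sample.int(W - (cc[2] - cc[1]), 1) - cc[1]
      shifted <- matrix(0, H, W)
      shifted[cbind(fg[, 1] + dy, fg[, 2] + dx)] <- 1
      M <- mo * shifted
      if (ok(M, sum(shifted))) return(M)
    }
    stop("placeMask: no valid placement found for ", context, " after ",
         maxRetries, " retries")
  })
}
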