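## Shared raster helpers. Images are H x W x 3 double arrays on the [0, 255]
## scale; binary masks are H x W matrices with values in {0, 1}.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded components do not
#' perturb each other or the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent child seed from a master seed
#'
#' Deterministic splitting of one master seed into per-component substreams
#' (mask, mode, transforms, ...) so each stage is independently reproducible.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the substream.
#' @param k Optional integer index for indexed substreams.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, tag, k = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  # modular arithmetic in doubles: all intermediates stay < 2^52
  v <- (as.double(seed) %% 2147483647) * 48271 %% 2147483647
  v <- (v + h * 69621 + as.double(k) * 16807) %% 2147483647
  as.integer(v)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

assertImage <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array")
  invisible(img)
}

assertMask <- function(m, what = "mask") {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  if (any(m != 0 & m != 1)) stop(what, " must be binary (0/1)")
  invisible(m)
}

#' Per-pixel luma of an RGB raster
#' @param img H x W x 3 array on the [0, 255] scale.
#' @return H x W matrix (Rec. 601 weights).
#' @keywords internal
luma <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

## HSV <-> RGB on (h in degrees [0, 360), s, v in [0, 1]); vectorised.
hsv2rgbMat <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i == 0; r[idx] <- v[idx]; g[idx] <- t[idx]; b[idx] <- p[idx]
  idx <- i == 1; r[idx] <- q[idx]; g[idx] <- v[idx]; b[idx] <- p[idx]
  idx <- i == 2; r[idx] <- p[idx]; g[idx] <- v[idx]; b[idx] <- t[idx]
  idx <- i == 3; r[idx] <- p[idx]; g[idx] <- q[idx]; b[idx] <- v[idx]
  idx <- i == 4; r[idx] <- t[idx]; g[idx] <- p[idx]; b[idx] <- v[idx]
  idx <- i >= 5; r[idx] <- v[idx]; g[idx] <- p[idx]; b[idx] <- q[idx]
  cbind(r, g, b)
}

rgb2hsvImage <- function(img) {
  px <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  grDevices::rgb2hsv(px, maxColorValue = 255)  # h, s, v rows in [0, 1]
}

hsvImage2rgb <- function(hsvm, dims) {
  m <- hsv2rgbMat(hsvm[1, ] * 360, hsvm[2, ], hsvm[3, ]) * 255
  array(c(m[, 1], m[, 2], m[, 3]), dim = c(dims, 3L))
}

#' Read an RGB image from a PNG file
#' @param path File path.
#' @return H x W x 3 array on the [0, 255] scale.
#' @export
readImageRGB <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write an RGB image to a PNG file (8-bit)
#' @param img H x W x 3 array on the [0, 255] scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeImageRGB <- function(img, path) {
  png::writePNG(round(clamp255(img)) / 255, path)
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#' @param path File path.
#' @return H x W matrix with values in {0, 1}.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x >= 0.5) * 1
}

#' Write a binary mask as a 0/255 PNG
#' @param mask H x W matrix with values in {0, 1}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

## EBImage bridges; EBImage stores images x-first so matrices are transposed
## at the boundary.
ebResizeMatrix <- function(m, h, w, filter = "bilinear") {
  t(EBImage::imageData(EBImage::resize(EBImage::as.Image(t(m)), w = w, h = h,
                                       filter = filter)))
}

#' Resize an RGB raster
#' @param img H x W x 3 array, [0, 255] scale.
#' @param h,w Target size in pixels.
#' @return Resized array.
#' @export
resizeImage <- function(img, h, w) {
  assertImage(img)
  out <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) out[, , c] <- ebResizeMatrix(img[, , c], h, w)
  clamp255(out)
}

#' Resize a binary mask (nearest neighbour, rebinarized)
#' @param mask H x W binary matrix.
#' @param h,w Target size in pixels.
#' @return Resized binary matrix.
#' @export
resizeMask <- function(mask, h, w) {
  (ebResizeMatrix(mask, h, w, filter = "none") >= 0.5) * 1
}

#' Gaussian blur of a single-channel raster
#'
#' Separable kernel truncated at `3*sigma`, so pixels farther than the
#' truncation radius from any non-zero input are exactly zero.
#'
#' @param m Matrix.
#' @param sigma Standard deviation in pixels.
#' @param border `"zero"` or `"replicate"` padding.
#' @return Blurred matrix.
#' @export
gaussianBlur <- function(m, sigma, border = c("zero", "replicate")) {
  border <- match.arg(border)
  gaussblur_cpp(m, sigma, if (border == "zero") 0L else 1L)
}

blurImage <- function(img, sigma) {
  out <- img
  for (c in 1:3) out[, , c] <- gaussblur_cpp(img[, , c], sigma, 1L)
  out
}
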