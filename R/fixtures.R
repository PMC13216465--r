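## Seeded procedural fixtures: mucosa-like "normal" endoscopy frames and
## texture patches. These stand in for clinical normals and external texture
## libraries so the whole pipeline builds, trains and tests offline.

#' Multi-octave value noise field
#'
#' Smooth organic-looking noise: random values on a coarse lattice,
#' bilinearly interpolated, with per-octave frequency doubling and
#' amplitude halving. Values are min-max normalised to [0, 1].
#'
#' @param size Side length in pixels.
#' @param octaves Number of octaves (>= 1).
#' @param baseCells Lattice cells of the first octave.
#' @return `size` x `size` matrix in [0, 1]. Draws from the current RNG
#'   stream; seed outside.
#' @keywords internal
valueNoise <- function(size, octaves = 3L, baseCells = 4L) {
  acc <- matrix(0, size, size)
  amp <- 1
  for (o in seq_len(octaves)) {
    cells <- baseCells * 2^(o - 1)
    g <- matrix(runif((cells + 1)^2), cells + 1L)
    p <- (seq_len(size) - 0.5) / size * cells
    i0 <- pmin(floor(p), cells - 1)
    f <- p - i0
    g00 <- g[i0 + 1, i0 + 1]; g01 <- g[i0 + 1, i0 + 2]
    g10 <- g[i0 + 2, i0 + 1]; g11 <- g[i0 + 2, i0 + 2]
    v <- outer(1 - f, 1 - f) * g00 + outer(1 - f, f) * g01 +
         outer(f, 1 - f) * g10 + outer(f, f) * g11
    acc <- acc + amp * v
    amp <- amp / 2
  }
  rng <- range(acc)
  if (rng[2] > rng[1]) acc <- (acc - rng[1]) / (rng[2] - rng[1])
  acc
}

#' Specification of a procedural mucosa-like image
#'
#' @param size Side length in pixels (>= 64; three encoder scales need it).
#' @param baseHue Base hue in degrees; mucosa lives in the wrap-around red
#'   band `[330, 25]`.
#' @param noiseOctaves Octaves of value noise (>= 1).
#' @param vignetteStrength Edge-darkening strength in [0, 1].
#' @param specularCount Number of specular highlight blobs (>= 0).
#' @param thumbnail Corner thumbnail emulating the dataset bias: `"none"`,
#'   `"green"` (as on normal frames) or `"black"`.
#' @param seed Integer seed; output is a pure function of the spec.
#' @return A `MucosaSpec` list.
#' @export
mucosaSpec <- function(size = 512L, baseHue = 350, noiseOctaves = 3L,
                       vignetteStrength = 0.35, specularCount = 5L,
                       thumbnail = c("none", "green", "black"), seed = 1L) {
  thumbnail <- match.arg(thumbnail)
  if (size < 64) stop("size must be >= 64")
  if (noiseOctaves < 1) stop("noiseOctaves must be >= 1")
  if (vignetteStrength < 0 || vignetteStrength > 1)
    stop("vignetteStrength must be in [0, 1]")
  if (specularCount < 0) stop("specularCount must be >= 0")
  hueOk <- (baseHue %% 360) >= 330 || (baseHue %% 360) <= 25
  if (!hueOk) stop("baseHue must lie in the red band [330, 25] (wrapping)")
  structure(list(size = as.integer(size), baseHue = baseHue %% 360,
                 noiseOctaves = as.integer(noiseOctaves),
                 vignetteStrength = vignetteStrength,
                 specularCount = as.integer(specularCount),
                 thumbnail = thumbnail, seed = as.integer(seed)),
            class = "MucosaSpec")
}

## thumbnail geometry: 40x40 px at offset (x = 8, y = size - 48); fully
## covered by the 64x64 evaluation bias patch.
thumbnailRows <- function(size) (size - 47):(size - 8)
thumbnailCols <- function(size) 9:48

#' Generate a mucosa-like RGB image
#'
#' Reddish-pink low-frequency texture with optional vignette, specular
#' highlights and a corner thumbnail. Deterministic for a fixed spec.
#'
#' @param spec A [mucosaSpec()].
#' @return H x W x 3 array on the [0, 255] scale (whole-valued).
#' @export
generateMucosa <- function(spec) {
  stopifnot(inherits(spec, "MucosaSpec"))
  s <- spec$size
  withSeed(spec$seed, {
    nh <- valueNoise(s, spec$noiseOctaves)
    ns <- valueNoise(s, spec$noiseOctaves)
    nv <- valueNoise(s, spec$noiseOctaves)
    hue <- spec$baseHue + 24 * (nh - mean(nh))
    sat <- 0.32 + 0.28 * ns
    val <- 0.45 + 0.35 * nv
    if (spec$vignetteStrength > 0) {
      ctr <- (s + 1) / 2
      d2 <- outer(((seq_len(s) - ctr) / (s / 2))^2,
                  ((seq_len(s) - ctr) / (s / 2))^2, "+")
      val <- val * (1 - spec$vignetteStrength * pmin(d2 / 2, 1))
    }
    rgbm <- hsv2rgbMat(as.vector(hue), as.vector(sat), as.vector(val)) * 255
    img <- array(c(rgbm[, 1], rgbm[, 2], rgbm[, 3]), dim = c(s, s, 3L))
    if (spec$specularCount > 0) {
      rows <- matrix(seq_len(s), s, s)
      cols <- t(rows)
      for (i in seq_len(spec$specularCount)) {
        cy <- runif(1, s * 0.1, s * 0.9)
        cx <- runif(1, s * 0.1, s * 0.9)
        r <- runif(1, 2, 6)
        w <- exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * r^2))
        for (c in 1:3) img[, , c] <- img[, , c] + w * (255 - img[, , c])
      }
    }
    if (spec$thumbnail != "none") {
      colr <- if (spec$thumbnail == "green") c(0, 180, 0) else c(0, 0, 0)
      for (c in 1:3)
        img[thumbnailRows(s), thumbnailCols(s), c] <- colr[c]
    }
    round(clamp255(img))
  })
}

#' Specification of a procedural texture patch
#'
#' @param size Side length in pixels.
#' @param palette List of RGB anchor vectors on the [0, 255] scale; the
#'   noise field is mapped through a linear gradient between the anchors.
#' @param granularity Feature size of the texture in pixels.
#' @param seed Integer seed.
#' @return A `TextureSpec` list.
#' @export
textureSpec <- function(size = 128L,
                        palette = list(c(92, 58, 32), c(168, 118, 72),
                                       c(56, 34, 20)),
                        granularity = 16, seed = 1L) {
  if (length(palette) < 1) stop("palette must have at least one RGB anchor")
  if (granularity <= 0) stop("granularity must be positive")
  structure(list(size = as.integer(size), palette = palette,
                 granularity = granularity, seed = as.integer(seed)),
            class = "TextureSpec")
}

#' Generate a texture patch
#'
#' Noise-driven gradient between the palette anchors plus fine-grained
#' per-octave detail. A degenerate (near-constant) result is rejected.
#'
#' @param spec A [textureSpec()].
#' @return H x W x 3 array, [0, 255] scale; per-channel sd is >= 5.
#' @export
generateTexture <- function(spec) {
  stopifnot(inherits(spec, "TextureSpec"))
  s <- spec$size
  img <- withSeed(spec$seed, {
    cells <- max(1L, as.integer(round(s / spec$granularity)))
    n <- valueNoise(s, octaves = 3L, baseCells = cells)
    k <- length(spec$palette)
    pal <- do.call(rbind, spec$palette)
    if (k == 1L) {
      base <- array(rep(pal[1, ], each = s * s), dim = c(s, s, 3L))
    } else {
      t <- as.vector(n) * (k - 1)
      i0 <- pmin(floor(t), k - 2)
      f <- t - i0
      base <- array(0, dim = c(s, s, 3L))
      for (c in 1:3)
        base[, , c] <- (1 - f) * pal[i0 + 1, c] + f * pal[i0 + 2, c]
    }
    base
  })
  img <- round(clamp255(img))
  sds <- apply(img, 3, sd)
  if (any(sds < 5))
    stop("degenerate texture: per-channel sd below 5 (got ",
         paste(round(sds, 2), collapse = ", "), ")")
  img
}

## small library of palettes cycled through by the fixture dataset builder
texturePalettes <- function() {
  list(
    list(c(92, 58, 32), c(172, 122, 78), c(50, 30, 16)),    # brown
    list(c(44, 28, 20), c(118, 84, 58), c(16, 10, 6)),      # dark brown
    list(c(150, 110, 80), c(214, 184, 146), c(104, 74, 52)),# tan
    list(c(120, 60, 50), c(196, 126, 106), c(74, 36, 30)),  # reddish
    list(c(70, 70, 64), c(148, 144, 130), c(40, 40, 34))    # grey
  )
}

#' Build an offline fixture dataset
#'
#' Writes `nNormal` mucosa-like PNGs and `nTextures` texture PNGs to a
#' directory together with a YAML manifest (filename, kind, per-file seed).
#' Rerunning with the same seed reproduces identical files.
#'
#' @param nNormal Number of normal (polyp-free) images.
#' @param nTextures Number of texture patches.
#' @param outDir Output directory.
#' @param seed Master seed.
#' @param size Normal image side length.
#' @param textureSize Texture patch side length.
#' @param thumbnail Thumbnail kind painted on normal images (the dataset
#'   bias of the corpus they emulate); default `"green"`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The manifest, invisibly (list with one entry per file).
#' @export
buildFixtureDataset <- function(nNormal, nTextures, outDir, seed = 0L,
                                size = 512L, textureSize = 128L,
                                thumbnail = "green", overwrite = FALSE) {
  if (dir.exists(outDir) && length(dir(outDir)) > 0 && !overwrite)
    stop("directory ", outDir, " is non-empty; use overwrite = TRUE")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  pals <- texturePalettes()
  for (i in seq_len(nNormal)) {
    fs <- deriveSeed(seed, "normal", i)
    spec <- withSeed(fs, mucosaSpec(
      size = size, baseHue = (330 + runif(1, 0, 55)) %% 360,
      vignetteStrength = runif(1, 0.2, 0.5),
      specularCount = sample(0:8, 1), thumbnail = thumbnail, seed = fs))
    fn <- sprintf("normal_%04d.png", i)
    writeImageRGB(generateMucosa(spec), file.path(outDir, fn))
    manifest[[length(manifest) + 1]] <-
      list(filename = fn, kind = "normal", seed = fs)
  }
  for (i in seq_len(nTextures)) {
    fs <- deriveSeed(seed, "texture", i)
    spec <- textureSpec(size = textureSize,
                        palette = pals[[(i - 1) %% length(pals) + 1]],
                        granularity = 8 + 8 * ((i - 1) %% 3), seed = fs)
    fn <- sprintf("texture_%04d.png", i)
    writeImageRGB(generateTexture(spec), file.path(outDir, fn))
    manifest[[length(manifest) + 1]] <-
      list(filename = fn, kind = "texture", seed = fs)
  }
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}
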