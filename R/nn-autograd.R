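## Minimal reverse-mode autodiff for the trainable segmentation head.
## Values are plain R arrays (feature maps H x W x C, or matrices for the
## coordinate-attention internals); each op pushes a backward closure onto a
## tape. Convolution and bilinear resampling kernels live in src/.

agTape <- function() {
  e <- new.env(parent = emptyenv())
  e$stack <- list()
  e
}

agPush <- function(tape, bw) {
  if (!is.null(tape)) tape$stack[[length(tape$stack) + 1L]] <- bw
  invisible(NULL)
}

#' @keywords internal
agNode <- function(val) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e
}

agAccum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Run the backward pass from an output node
#' @param tape Tape returned by `agTape()`.
#' @param node Output node.
#' @param seed Gradient of the loss with respect to `node` (same shape).
#' @keywords internal
agBackward <- function(tape, node, seed) {
  node$grad <- seed
  for (i in rev(seq_along(tape$stack))) tape$stack[[i]]()
  invisible(NULL)
}

agConv <- function(tape, x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  out <- agNode(conv2d_fwd_cpp(x$val, W$val, as.numeric(b$val), k, stride,
                               pad))
  agPush(tape, function() {
    r <- conv2d_bwd_cpp(x$val, W$val, out$grad, k, stride, pad)
    agAccum(x, r$dX)
    agAccum(W, r$dW)
    agAccum(b, as.numeric(r$db))
  })
  out
}

## per-channel instance normalisation with affine parameters (channels as
## columns of an (H*W) x C matrix view)
agNormChan <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$val)
  M <- x$val; dim(M) <- c(d[1] * d[2], d[3])
  mu <- colMeans(M)
  xc <- sweep(M, 2, mu)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma$val, "*"), 2, beta$val, "+")
  dim(y) <- d
  out <- agNode(y)
  agPush(tape, function() {
    dy <- out$grad; dim(dy) <- dim(M)
    agAccum(gamma, colSums(dy * xhat))
    agAccum(beta, colSums(dy))
    dxh <- sweep(dy, 2, gamma$val, "*")
    dx <- sweep(sweep(dxh, 2, colMeans(dxh)) -
                  sweep(xhat, 2, colMeans(dxh * xhat), "*"),
                2, inv, "*")
    dim(dx) <- d
    agAccum(x, dx)
  })
  out
}

## column-wise instance normalisation for matrix activations (rows =
## positions, cols = channels)
agNormCols <- function(tape, x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x$val)
  v <- colMeans(sweep(x$val, 2, mu)^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x$val, 2, mu), 2, inv, "*")
  out <- agNode(sweep(sweep(xhat, 2, gamma$val, "*"), 2, beta$val, "+"))
  agPush(tape, function() {
    dy <- out$grad
    agAccum(gamma, colSums(dy * xhat))
    agAccum(beta, colSums(dy))
    dxh <- sweep(dy, 2, gamma$val, "*")
    t1 <- sweep(dxh, 2, colMeans(dxh))
    t2 <- sweep(xhat, 2, colMeans(dxh * xhat), "*")
    agAccum(x, sweep(t1 - t2, 2, inv, "*"))
  })
  out
}

## parameter-free per-channel instance normalisation (numerical
## conditioning of activations whose scale varies strongly across images)
agNormChan0 <- function(tape, x, eps = 1e-5) {
  d <- dim(x$val)
  M <- x$val; dim(M) <- c(d[1] * d[2], d[3])
  mu <- colMeans(M)
  xc <- sweep(M, 2, mu)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2, inv, "*")
  y <- xhat; dim(y) <- d
  out <- agNode(y)
  agPush(tape, function() {
    dy <- out$grad; dim(dy) <- dim(M)
    dx <- sweep(sweep(dy, 2, colMeans(dy)) -
                  sweep(xhat, 2, colMeans(dy * xhat), "*"),
                2, inv, "*")
    dim(dx) <- d
    agAccum(x, dx)
  })
  out
}

agReLU <- function(tape, x) {
  out <- agNode(pmax(x$val, 0))
  agPush(tape, function() agAccum(x, out$grad * (x$val > 0)))
  out
}

agSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  out <- agNode(s)
  agPush(tape, function() agAccum(x, out$grad * s * (1 - s)))
  out
}

agAdd <- function(tape, x, y) {
  out <- agNode(x$val + y$val)
  agPush(tape, function() {
    agAccum(x, out$grad)
    agAccum(y, out$grad)
  })
  out
}

## multiply every channel by a constant single-channel map (no gradient
## into the map: attention maps come from the frozen encoder)
agMulMap <- function(tape, x, m) {
  mv <- as.vector(m)  # recycles across channels
  out <- agNode(x$val * mv)
  agPush(tape, function() agAccum(x, out$grad * mv))
  out
}

agUp2 <- function(tape, x) {
  d <- dim(x$val)
  out <- agNode(upsample2x_fwd_cpp(x$val))
  agPush(tape, function()
    agAccum(x, upsample2x_bwd_cpp(out$grad, d[1], d[2])))
  out
}

agMatmul <- function(tape, x, W) {
  out <- agNode(x$val %*% W$val)
  agPush(tape, function() {
    agAccum(x, out$grad %*% t(W$val))
    agAccum(W, crossprod(x$val, out$grad))
  })
  out
}

agAddBiasCols <- function(tape, x, b) {
  out <- agNode(sweep(x$val, 2, b$val, "+"))
  agPush(tape, function() {
    agAccum(x, out$grad)
    agAccum(b, colSums(out$grad))
  })
  out
}

agRbind <- function(tape, x, y) {
  nx <- nrow(x$val)
  out <- agNode(rbind(x$val, y$val))
  agPush(tape, function() {
    agAccum(x, out$grad[seq_len(nx), , drop = FALSE])
    agAccum(y, out$grad[-seq_len(nx), , drop = FALSE])
  })
  out
}

agRows <- function(tape, x, rows) {
  out <- agNode(x$val[rows, , drop = FALSE])
  agPush(tape, function() {
    g <- x$val * 0
    g[rows, ] <- out$grad
    agAccum(x, g)
  })
  out
}

## mean over width -> (H, C); mean over height -> (W, C)
agMeanW <- function(tape, x) {
  d <- dim(x$val)
  out <- agNode(apply(x$val, 3, rowMeans))
  agPush(tape, function() {
    dx <- x$val * 0
    for (c in seq_len(d[3]))
      dx[, , c] <- matrix(out$grad[, c] / d[2], d[1], d[2])
    agAccum(x, dx)
  })
  out
}

agMeanH <- function(tape, x) {
  d <- dim(x$val)
  out <- agNode(apply(x$val, 3, colMeans))
  agPush(tape, function() {
    dx <- x$val * 0
    for (c in seq_len(d[3]))
      dx[, , c] <- matrix(out$grad[, c] / d[1], d[1], d[2], byrow = TRUE)
    agAccum(x, dx)
  })
  out
}

## out[h,w,c] = x[h,w,c] * ah[h,c] * aw[w,c] (coordinate attention gate)
agScaleHW <- function(tape, x, ah, aw) {
  d <- dim(x$val)
  y <- x$val
  for (c in seq_len(d[3]))
    y[, , c] <- y[, , c] * outer(ah$val[, c], aw$val[, c])
  out <- agNode(y)
  agPush(tape, function() {
    dy <- out$grad
    dx <- dy
    dah <- ah$val * 0; daw <- aw$val * 0
    for (c in seq_len(d[3])) {
      g <- outer(ah$val[, c], aw$val[, c])
      dx[, , c] <- dy[, , c] * g
      dah[, c] <- (dy[, , c] * x$val[, , c]) %*% aw$val[, c]
      daw[, c] <- t(dy[, , c] * x$val[, , c]) %*% ah$val[, c]
    }
    agAccum(x, dx)
    agAccum(ah, dah)
    agAccum(aw, daw)
  })
  out
}
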