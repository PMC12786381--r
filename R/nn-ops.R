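## 3D convolution primitives (pure R, im2col + GEMM).
##
## Tensors are channel-first arrays c(C, D, H, W): C color/feature channels,
## D the view ("depth") axis, H x W pixels.  A convolution geometry caches
## the im2col index matrix and the transposed scatter operator so that the
## forward pass, the data gradient (= transposed convolution forward) and
## the weight gradient are all single matrix products.

.convGeomCache <- new.env(parent = emptyenv())

convGeom <- function(in_shape, kernel, stride, pad) {
  key <- paste(c(in_shape, kernel, stride, pad), collapse = "_")
  g <- .convGeomCache[[key]]
  if (!is.null(g)) return(g)
  C <- in_shape[1]; D <- in_shape[2]; H <- in_shape[3]; W <- in_shape[4]
  kd <- kernel[1]; kh <- kernel[2]; kw <- kernel[3]
  sd_ <- stride[1]; sh <- stride[2]; sw <- stride[3]
  pd <- pad[1]; ph <- pad[2]; pw <- pad[3]
  Dp <- D + 2 * pd; Hp <- H + 2 * ph; Wp <- W + 2 * pw
  OD <- (Dp - kd) %/% sd_ + 1L
  OH <- (Hp - kh) %/% sh + 1L
  OW <- (Wp - kw) %/% sw + 1L
  stopifnot(OD >= 1, OH >= 1, OW >= 1)
  rg <- expand.grid(c = seq_len(C), id = seq_len(kd),
                    ih = seq_len(kh), iw = seq_len(kw))
  jg <- expand.grid(od = seq_len(OD), oh = seq_len(OH), ow = seq_len(OW))
  dmat <- outer(rg$id, (jg$od - 1L) * sd_, "+")
  hmat <- outer(rg$ih, (jg$oh - 1L) * sh, "+")
  wmat <- outer(rg$iw, (jg$ow - 1L) * sw, "+")
  idx <- rg$c + C * ((dmat - 1L) + Dp * ((hmat - 1L) + Hp * (wmat - 1L)))
  storage.mode(idx) <- "integer"
  scat <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                               x = 1, dims = c(C * Dp * Hp * Wp, length(idx)))
  g <- list(in_shape = in_shape, kernel = kernel, stride = stride, pad = pad,
            padded = c(C, Dp, Hp, Wp), out_spatial = c(OD, OH, OW),
            R = nrow(idx), P = ncol(idx), idx = idx, scat = scat)
  .convGeomCache[[key]] <- g
  g
}

padTensor <- function(x, g) {
  p <- g$pad
  if (all(p == 0)) return(x)
  d <- g$in_shape
  out <- array(0, g$padded)
  out[, p[1] + seq_len(d[2]), p[2] + seq_len(d[3]), p[3] + seq_len(d[4])] <- x
  out
}

unpadTensor <- function(x, g) {
  p <- g$pad
  if (all(p == 0)) return(x)
  d <- g$in_shape
  x[, p[1] + seq_len(d[2]), p[2] + seq_len(d[3]), p[3] + seq_len(d[4]),
    drop = FALSE]
}

im2col <- function(x, g) {
  xp <- padTensor(x, g)
  matrix(xp[g$idx], g$R, g$P)
}

col2im <- function(cols, g) {
  v <- as.vector(g$scat %*% as.vector(cols))
  unpadTensor(array(v, g$padded), g)
}

## Weights for a conv layer mapping C -> K channels are stored as a
## K x (C*kd*kh*kw) matrix (kernel elements ordered channel-fastest,
## matching im2col rows), bias as length-K vector.

convInit <- function(C, K, kernel) {
  fan_in <- C * prod(kernel)
  fan_out <- K * prod(kernel)
  list(W = xavierMatrix(K, fan_in, fan_in = fan_in, fan_out = fan_out),
       b = numeric(K))
}

## Forward convolution: returns array c(K, OD, OH, OW); caches im2col
## columns in attr "cols" for the weight gradient.
convForward <- function(x, W, b, g, keep_cols = FALSE) {
  cols <- im2col(x, g)
  y <- W %*% cols + b
  out <- array(y, c(nrow(W), g$out_spatial))
  if (keep_cols) attr(out, "cols") <- cols
  out
}

## Gradient of the convolution w.r.t. its input: dY is c(K, OD, OH, OW).
convBackwardData <- function(dy, W, g) {
  dcols <- crossprod(W, matrix(dy, nrow(W)))
  col2im(dcols, g)
}

## Gradient w.r.t. weights/bias; `cols` from the cached forward pass.
convBackwardParams <- function(dy, cols, K) {
  dym <- matrix(dy, K)
  list(W = dym %*% t(cols), b = rowSums(dym))
}

## Transposed convolution ("deconvolution") with the same geometry g:
## maps a c(K, OD, OH, OW) input back to c(C, D, H, W).  Weight layout is
## identical to the paired convolution (K x C*k^3); bias is per *output*
## channel (length C).
tconvForward <- function(u, W, b, g) {
  cols <- crossprod(W, matrix(u, nrow(W)))
  y <- col2im(cols, g)
  C <- g$in_shape[1]
  y + array(rep(b, prod(g$in_shape) / C), g$in_shape)  # b recycles over C first
}

tconvBackwardData <- function(dout, W, g) {
  cols <- im2col(dout, g)
  array(W %*% cols, c(nrow(W), g$out_spatial))
}

tconvBackwardParams <- function(u, dout, g) {
  K <- dim(u)[1]
  dcols <- im2col(dout, g)
  dW <- matrix(u, K) %*% t(dcols)
  C <- g$in_shape[1]
  db <- rowSums(matrix(dout, C))
  list(W = dW, b = db)
}

## Brute-force 3D convolution oracle (nested loops); used only in tests
## as the independent reference for the im2col implementation.
convForwardNaive <- function(x, W, b, g) {
  C <- g$in_shape[1]; k <- g$kernel; s <- g$stride
  os <- g$out_spatial; K <- nrow(W)
  xp <- padTensor(x, g)
  Warr <- array(W, c(K, C, k[1], k[2], k[3]))
  out <- array(0, c(K, os))
  for (kk in seq_len(K)) for (od in seq_len(os[1]))
    for (oh in seq_len(os[2])) for (ow in seq_len(os[3])) {
      acc <- 0
      for (cc in seq_len(C)) for (a in seq_len(k[1]))
        for (bb in seq_len(k[2])) for (ccc in seq_len(k[3]))
          acc <- acc + Warr[kk, cc, a, bb, ccc] *
            xp[cc, (od - 1) * s[1] + a, (oh - 1) * s[2] + bb,
               (ow - 1) * s[3] + ccc]
      out[kk, od, oh, ow] <- acc + b[kk]
    }
  out
}
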