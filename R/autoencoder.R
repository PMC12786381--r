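## Direction-aware 3D convolutional autoencoder over the six-view tensor.
##
## Global branch: n conv3d layers (LeakyReLU between) -> linear latent v;
## decoder mirrors with transposed convolutions and a sigmoid output.
## Directional branch: the six views are grouped into the fixed pairs
## (front, right), (back, bottom), (top, left) and each pair runs through
## its own (non-weight-shared) conv path; pooled maps are concatenated
## into the local spatial feature x3 exported to fusion.

#' Configuration for the spatial autoencoder
#'
#' @param H,W view resolution in pixels.
#' @param latent_dim length of the global latent embedding v.
#' @param enc_channels channel widths of the encoder conv stack (one
#'   entry per layer; spatial stride 2 per layer, view axis unstrided).
#' @param dir_channels channel widths of each directional conv path.
#' @param negative_slope LeakyReLU slope.
#' @param encoder_bias use bias terms in the encoder/directional
#'   convolutions. Off by default: a bias-free encoder maps empty
#'   background to exactly zero activations at every depth, which keeps
#'   saliency maps anchored on molecular geometry and makes the
#'   zero-input Grad-CAM identity hold for trained models too.
#' @param decoder_input "latent" reconstructs from the global latent v
#'   (pretraining objective); "directional" is the literal variant that
#'   seeds the decoder with the directional feature x3.
#' @return a config list.
#' @export
spatialConfig <- function(H = 64L, W = 64L, latent_dim = 128L,
                          enc_channels = c(16L, 32L, 64L),
                          dir_channels = c(8L, 32L),
                          negative_slope = 0.01,
                          encoder_bias = FALSE,
                          decoder_input = c("latent", "directional")) {
  stopifnot(latent_dim >= 1, length(enc_channels) >= 1)
  list(H = as.integer(H), W = as.integer(W),
       latent_dim = as.integer(latent_dim),
       enc_channels = as.integer(enc_channels),
       dir_channels = as.integer(dir_channels),
       negative_slope = negative_slope,
       encoder_bias = isTRUE(encoder_bias),
       decoder_input = match.arg(decoder_input))
}

encGeoms <- function(cfg) {
  shapes <- list(c(4L, 6L, cfg$H, cfg$W))
  geoms <- list()
  for (k in seq_along(cfg$enc_channels)) {
    g <- convGeom(shapes[[k]], kernel = c(3, 3, 3), stride = c(1, 2, 2),
                  pad = c(1, 1, 1))
    geoms[[k]] <- g
    shapes[[k + 1]] <- c(cfg$enc_channels[k], g$out_spatial)
  }
  list(geoms = geoms, shapes = shapes)
}

dirGeoms <- function(cfg) {
  shapes <- list(c(4L, 2L, cfg$H, cfg$W))
  geoms <- list()
  for (k in seq_along(cfg$dir_channels)) {
    g <- convGeom(shapes[[k]], kernel = c(3, 3, 3), stride = c(1, 2, 2),
                  pad = c(1, 1, 1))
    geoms[[k]] <- g
    shapes[[k + 1]] <- c(cfg$dir_channels[k], g$out_spatial)
  }
  list(geoms = geoms, shapes = shapes)
}

#' Directional feature length d3 implied by a spatial config
#' @param cfg a \code{\link{spatialConfig}}.
#' @return integer d3 (three pooled directional paths concatenated).
#' @export
directionalDim <- function(cfg = spatialConfig()) {
  dg <- dirGeoms(cfg)
  last <- dg$shapes[[length(dg$shapes)]]
  3L * last[1] * last[2]   # channels x views, pooled over H, W, per path
}

#' Initialize autoencoder parameters
#'
#' Weights are Glorot-uniform from a seeded RNG; identical seeds give
#' bitwise-identical parameters.
#'
#' @param cfg a \code{\link{spatialConfig}}.
#' @param seed integer RNG seed.
#' @return model parameter list (encoder, latent maps, decoder,
#'   directional paths, config).
#' @export
initSpatialAutoencoder <- function(cfg = spatialConfig(), seed = 0L) {
  eg <- encGeoms(cfg)
  nl <- length(cfg$enc_channels)
  flat <- prod(eg$shapes[[nl + 1]])
  withSeed(seed, {
    enc <- list()
    inCh <- 4L
    for (k in seq_len(nl)) {
      enc[[k]] <- convInit(inCh, cfg$enc_channels[k], c(3, 3, 3))
      inCh <- cfg$enc_channels[k]
    }
    dec <- list()
    for (k in rev(seq_len(nl))) {
      outCh <- if (k == 1) 4L else cfg$enc_channels[k - 1]
      ## tconv uses the geometry of encoder layer k, weights K x (C*27)
      dec[[nl - k + 1]] <- list(
        W = xavierMatrix(cfg$enc_channels[k], outCh * 27,
                         fan_in = cfg$enc_channels[k] * 27,
                         fan_out = outCh * 27),
        b = numeric(outCh))
    }
    dirs <- lapply(1:3, function(p) {
      inc <- 4L
      lapply(seq_along(cfg$dir_channels), function(k) {
        l <- convInit(inc, cfg$dir_channels[k], c(3, 3, 3))
        inc <<- cfg$dir_channels[k]
        l
      })
    })
    list(cfg = cfg,
         enc = enc,
         to_latent = list(W = xavierMatrix(cfg$latent_dim, flat),
                          b = numeric(cfg$latent_dim)),
         from_latent = list(W = xavierMatrix(flat, cfg$latent_dim),
                            b = numeric(flat)),
         dec = dec,
         dirs = dirs,
         seed = as.integer(seed))
  })
}

asViewArray <- function(t) {
  if (is(t, "ViewTensor")) t@data else t
}

checkViewShape <- function(x, cfg) {
  d <- dim(x)
  if (length(d) != 4 || d[1] != 4 || d[2] != 6 || d[3] != cfg$H ||
      d[4] != cfg$W)
    stopMv("ShapeError", "expected tensor 4x6x%dx%d, got %s",
           cfg$H, cfg$W, paste(d, collapse = "x"))
  invisible(TRUE)
}

## Forward through the global encoder; cache pre-activations for backprop.
encodeForwardInternal <- function(x, model, keep = FALSE) {
  cfg <- model$cfg
  eg <- encGeoms(cfg)
  h <- x
  cache <- list(inputs = list(), pre = list(), cols = list())
  for (k in seq_along(model$enc)) {
    if (keep) cache$inputs[[k]] <- h
    z <- convForward(h, model$enc[[k]]$W, model$enc[[k]]$b, eg$geoms[[k]],
                     keep_cols = keep)
    if (keep) {
      cache$cols[[k]] <- attr(z, "cols")
      attr(z, "cols") <- NULL
      cache$pre[[k]] <- z
    }
    h <- leakyRelu(z, cfg$negative_slope)
  }
  flat <- as.vector(h)
  v <- as.vector(model$to_latent$W %*% flat + model$to_latent$b)
  if (keep) {
    cache$flat <- flat
    cache$geoms <- eg
  }
  list(v = v, cache = cache)
}

## Backprop dL/dv through the encoder; returns parameter grads and
## optionally dL/d(input tensor).
encodeBackwardInternal <- function(dv, model, cache, want_dx = FALSE,
                                   batch_linear = FALSE) {
  cfg <- model$cfg
  grads <- if (batch_linear) list()
           else list(to_latent = list(W = outer(dv, cache$flat), b = dv))
  dflat <- as.vector(crossprod(model$to_latent$W, dv))
  nl <- length(model$enc)
  lastShape <- dim(leakyRelu(cache$pre[[nl]], cfg$negative_slope))
  dh <- array(dflat, lastShape)
  grads$enc <- vector("list", nl)
  for (k in rev(seq_len(nl))) {
    dz <- dh * leakyReluGrad(cache$pre[[k]], cfg$negative_slope)
    grads$enc[[k]] <- convBackwardParams(dz, cache$cols[[k]],
                                         nrow(model$enc[[k]]$W))
    if (k > 1 || want_dx)
      dh <- convBackwardData(dz, model$enc[[k]]$W, cache$geoms$geoms[[k]])
  }
  if (want_dx) grads$dx <- dh
  grads
}

#' Encode a view tensor into the global latent embedding
#'
#' @param t a \linkS4class{ViewTensor} (or bare 4 x 6 x H x W array).
#' @param model parameters from \code{\link{initSpatialAutoencoder}} or
#'   \code{\link{trainAutoencoder}}.
#' @return numeric latent vector of length \code{latent_dim}.
#' @export
encodeGlobal <- function(t, model) {
  x <- asViewArray(t)
  checkViewShape(x, model$cfg)
  encodeForwardInternal(x, model)$v
}

decodeForwardInternal <- function(v, model, keep = FALSE) {
  cfg <- model$cfg
  eg <- encGeoms(cfg)
  nl <- length(model$enc)
  if (length(v) != cfg$latent_dim)
    stopMv("ShapeError", "latent length %d, expected %d", length(v),
           cfg$latent_dim)
  cache <- list(v = v)
  u <- as.vector(model$from_latent$W %*% v + model$from_latent$b)
  pre0 <- array(u, eg$shapes[[nl + 1]])
  if (keep) cache$pre0 <- pre0
  h <- leakyRelu(pre0, cfg$negative_slope)
  cache$inputs <- list(); cache$pre <- list()
  for (k in seq_len(nl)) {
    gidx <- nl - k + 1           # decoder layer k inverts encoder layer gidx
    if (keep) cache$inputs[[k]] <- h
    z <- tconvForward(h, model$dec[[k]]$W, model$dec[[k]]$b, eg$geoms[[gidx]])
    if (keep) cache$pre[[k]] <- z
    h <- if (k < nl) leakyRelu(z, cfg$negative_slope) else sigmoid(z)
  }
  if (keep) { cache$out <- h; cache$geoms <- eg }
  list(y = h, cache = cache)
}

decodeBackwardInternal <- function(dy, model, cache, batch_linear = FALSE) {
  cfg <- model$cfg
  nl <- length(model$enc)
  grads <- list(dec = vector("list", nl))
  dh <- dy
  for (k in rev(seq_len(nl))) {
    gidx <- nl - k + 1
    dz <- if (k < nl) dh * leakyReluGrad(cache$pre[[k]], cfg$negative_slope)
          else dh * cache$out * (1 - cache$out)
    grads$dec[[k]] <- tconvBackwardParams(cache$inputs[[k]], dz,
                                          cache$geoms$geoms[[gidx]])
    dh <- tconvBackwardData(dz, model$dec[[k]]$W, cache$geoms$geoms[[gidx]])
  }
  dpre0 <- as.vector(dh * leakyReluGrad(cache$pre0, cfg$negative_slope))
  if (batch_linear) grads$dpre0 <- dpre0
  else grads$from_latent <- list(W = outer(dpre0, cache$v), b = dpre0)
  grads$dv <- as.vector(crossprod(model$from_latent$W, dpre0))
  grads
}

#' Decode a latent embedding back to view-tensor shape
#'
#' The final sigmoid bounds all values to [0, 1]; output shape is
#' exactly 4 x 6 x H x W.
#'
#' @param v numeric latent vector.
#' @param model autoencoder parameters.
#' @return a 4 x 6 x H x W array.
#' @export
decodeViews <- function(v, model) {
  decodeForwardInternal(v, model)$y
}

#' Reconstruction loss (mean per-sample sum of squared errors)
#'
#' \eqn{L = (1/N) \sum_i ||y_i - \hat y_i||_2^2} over all elements of each
#' sample, following the training objective literally; set
#' \code{normalized = TRUE} to divide by the element count as well.
#'
#' @param y,y_hat single tensors (ViewTensor or array) or lists of them.
#' @param normalized divide by elements per sample.
#' @return scalar loss.
#' @export
reconstructionLoss <- function(y, y_hat, normalized = FALSE) {
  ys <- if (is.list(y)) lapply(y, asViewArray) else list(asViewArray(y))
  yh <- if (is.list(y_hat)) lapply(y_hat, asViewArray)
        else list(asViewArray(y_hat))
  if (length(ys) != length(yh))
    stopMv("ShapeError", "batch sizes differ: %d vs %d", length(ys),
           length(yh))
  if (length(ys) < 1) stopMv("ShapeError", "empty batch")
  tot <- 0
  for (i in seq_along(ys)) {
    if (!identical(dim(ys[[i]]), dim(yh[[i]])))
      stopMv("ShapeError", "sample %d shape mismatch", i)
    d <- ys[[i]] - yh[[i]]
    sse <- sum(d * d)
    tot <- tot + if (normalized) sse / length(d) else sse
  }
  tot / length(ys)
}

#' Group the six views into the three directional pairs
#'
#' Fixed pairing: g1 = (front, right), g2 = (back, bottom),
#' g3 = (top, left); each group is a 4 x 2 x H x W slice.
#'
#' @param t a \linkS4class{ViewTensor} or 4 x 6 x H x W array.
#' @return list with elements g1, g2, g3 and attribute "view_indices".
#' @export
groupViews <- function(t) {
  x <- asViewArray(t)
  d <- dim(x)
  if (length(d) != 4 || d[2] != 6)
    stopMv("ShapeError", "expected 6 views, got shape %s",
           paste(d, collapse = "x"))
  idx <- list(g1 = c(1L, 2L), g2 = c(3L, 4L), g3 = c(5L, 6L))
  out <- lapply(idx, function(i) x[, i, , , drop = FALSE])
  attr(out, "view_indices") <- idx
  out
}

dirForwardInternal <- function(groups, model, keep = FALSE) {
  cfg <- model$cfg
  dg <- dirGeoms(cfg)
  feats <- list(); caches <- list()
  for (p in 1:3) {
    h <- groups[[p]]
    cache <- list(inputs = list(), pre = list(), cols = list())
    for (k in seq_along(model$dirs[[p]])) {
      if (keep) cache$inputs[[k]] <- h
      z <- convForward(h, model$dirs[[p]][[k]]$W, model$dirs[[p]][[k]]$b,
                       dg$geoms[[k]], keep_cols = keep)
      if (keep) {
        cache$cols[[k]] <- attr(z, "cols"); attr(z, "cols") <- NULL
        cache$pre[[k]] <- z
      }
      h <- leakyRelu(z, cfg$negative_slope)
    }
    ## pool over H, W; keep channels x views
    a <- apply(h, c(1, 2), mean)
    feats[[p]] <- as.vector(a)
    if (keep) { cache$last <- h; caches[[p]] <- cache }
  }
  x3 <- c(feats[[1]], feats[[2]], feats[[3]])
  attr(x3, "a1") <- feats[[1]]; attr(x3, "a2") <- feats[[2]]
  attr(x3, "a3") <- feats[[3]]
  list(x3 = x3, feats = feats, caches = caches, geoms = dg)
}

#' Direction-aware encoding of the three view groups
#'
#' Each group passes through its own convolutional path (no weight
#' sharing); pooled per-channel/per-view activations a1, a2, a3 are
#' concatenated into the local spatial feature x3 of length
#' \code{\link{directionalDim}(cfg)}.
#'
#' @param groups result of \code{\link{groupViews}} (or a ViewTensor,
#'   which is grouped first).
#' @param model autoencoder parameters.
#' @return numeric x3 with attributes a1, a2, a3.
#' @export
directionalEncode <- function(groups, model) {
  if (is(groups, "ViewTensor") ||
      (is.array(groups) && length(dim(groups)) == 4))
    groups <- groupViews(groups)
  if (length(groups) != 3)
    stopMv("ShapeError", "expected 3 view groups")
  for (g in groups) {
    d <- dim(g)
    if (length(d) != 4 || d[1] != 4 || d[2] != 2 ||
        d[3] != model$cfg$H || d[4] != model$cfg$W)
      stopMv("ShapeError", "bad group shape %s", paste(d, collapse = "x"))
  }
  r <- dirForwardInternal(groups, model)
  r$x3
}

#' Full spatial feature pass for one molecule
#'
#' Convenience wrapper returning both the global latent v and the
#' directional feature x3 for a rendered tensor.
#'
#' @param t a \linkS4class{ViewTensor}.
#' @param model autoencoder parameters.
#' @return list(v, x3).
#' @export
spatialFeatures <- function(t, model) {
  x <- asViewArray(t)
  checkViewShape(x, model$cfg)
  list(v = encodeGlobal(x, model),
       x3 = directionalEncode(groupViews(x), model))
}

flattenParams <- function(model) {
  out <- list()
  for (k in seq_along(model$enc)) {
    out[[paste0("encW", k)]] <- model$enc[[k]]$W
    out[[paste0("encB", k)]] <- model$enc[[k]]$b
  }
  out$latW <- model$to_latent$W; out$latB <- model$to_latent$b
  out$upW <- model$from_latent$W; out$upB <- model$from_latent$b
  for (k in seq_along(model$dec)) {
    out[[paste0("decW", k)]] <- model$dec[[k]]$W
    out[[paste0("decB", k)]] <- model$dec[[k]]$b
  }
  out
}

unflattenParams <- function(model, flat) {
  for (k in seq_along(model$enc)) {
    model$enc[[k]]$W <- flat[[paste0("encW", k)]]
    model$enc[[k]]$b <- flat[[paste0("encB", k)]]
  }
  model$to_latent$W <- flat$latW; model$to_latent$b <- flat$latB
  model$from_latent$W <- flat$upW; model$from_latent$b <- flat$upB
  for (k in seq_along(model$dec)) {
    model$dec[[k]]$W <- flat[[paste0("decW", k)]]
    model$dec[[k]]$b <- flat[[paste0("decB", k)]]
  }
  model
}

#' Train the autoencoder by reconstruction
#'
#' Full-batch Adam on the mean per-sample sum-of-squares reconstruction
#' loss. Training is deterministic given (dataset order, seed): the
#' reported trajectory is reproducible bitwise.
#'
#' @param dataset list of \linkS4class{ViewTensor}s (>= 2).
#' @param cfg a \code{\link{spatialConfig}}.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization.
#' @param verbose print per-epoch loss.
#' @return list(model, loss): trained parameters and the per-epoch loss
#'   trajectory (epoch-start loss, including a final evaluation, length
#'   epochs + 1).
#' @export
trainAutoencoder <- function(dataset, cfg = spatialConfig(), epochs = 50L,
                             lr = 1e-3, seed = 0L, verbose = FALSE) {
  if (!is.list(dataset) || length(dataset) < 2)
    stopMv("InputError", "need at least 2 training tensors")
  xs <- lapply(dataset, asViewArray)
  for (x in xs) checkViewShape(x, cfg)
  model <- initSpatialAutoencoder(cfg, seed)
  params <- flattenParams(model)
  opt <- adamInit(params)
  N <- length(xs)
  losses <- numeric(0)
  flatLen <- nrow(model$from_latent$W)
  for (ep in seq_len(epochs)) {
    grads <- lapply(params, function(p) p * 0)
    loss <- 0
    DV <- matrix(0, cfg$latent_dim, N); FLAT <- matrix(0, flatLen, N)
    DP0 <- matrix(0, flatLen, N); VS <- matrix(0, cfg$latent_dim, N)
    for (i in seq_len(N)) {
      enc <- encodeForwardInternal(xs[[i]], model, keep = TRUE)
      dec <- decodeForwardInternal(enc$v, model, keep = TRUE)
      resid <- dec$y - xs[[i]]
      loss <- loss + sum(resid * resid)
      dy <- 2 * resid / N
      gdec <- decodeBackwardInternal(dy, model, dec$cache,
                                     batch_linear = TRUE)
      genc <- encodeBackwardInternal(gdec$dv, model, enc$cache,
                                     batch_linear = TRUE)
      DV[, i] <- gdec$dv; FLAT[, i] <- enc$cache$flat
      DP0[, i] <- gdec$dpre0; VS[, i] <- enc$v
      for (k in seq_along(model$enc)) {
        grads[[paste0("encW", k)]] <- grads[[paste0("encW", k)]] +
          genc$enc[[k]]$W
        grads[[paste0("encB", k)]] <- grads[[paste0("encB", k)]] +
          genc$enc[[k]]$b
      }
      for (k in seq_along(model$dec)) {
        grads[[paste0("decW", k)]] <- grads[[paste0("decW", k)]] +
          gdec$dec[[k]]$W
        grads[[paste0("decB", k)]] <- grads[[paste0("decB", k)]] +
          gdec$dec[[k]]$b
      }
    }
    grads$latW <- tcrossprod(DV, FLAT); grads$latB <- rowSums(DV)
    grads$upW <- tcrossprod(DP0, VS); grads$upB <- rowSums(DP0)
    if (!isTRUE(cfg$encoder_bias))
      for (k in seq_along(model$enc))
        grads[[paste0("encB", k)]][] <- 0
    loss <- loss / N
    if (!is.finite(loss))
      stopMv("TrainingDivergedError", "non-finite loss at epoch %d", ep)
    losses <- c(losses, loss)
    step <- adamStep(params, grads, opt, lr = lr)
    params <- step$params; opt <- step$state
    model <- unflattenParams(model, params)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, loss))
  }
  final <- mean(vapply(xs, function(x) {
    yhat <- decodeForwardInternal(encodeForwardInternal(x, model)$v, model)$y
    sum((yhat - x)^2)
  }, numeric(1)))
  losses <- c(losses, final)
  list(model = model, loss = losses)
}
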