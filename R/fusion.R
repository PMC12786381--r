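## Self-Controlled gated Residual Network (SCRN) fusion of the three
## drug modalities: per-modality linear projection into a shared latent
## space, softmax gating, weighted concatenation of the ORIGINAL
## modality vectors, then a two-layer residual 1D convolutional
## refinement y = h2 + X.

#' SCRN configuration
#'
#' @param d1,d2,d3 modality dimensions (fingerprint, graph embedding,
#'   directional spatial feature).
#' @param dz shared projection dimension.
#' @param kernel odd 1D convolution kernel size for the refinement.
#' @param negative_slope LeakyReLU slope for f1, f2.
#' @param gate_mode "scalar" (default): each projected z_i is reduced to
#'   one logit and the softmax runs over three scalars, giving one weight
#'   per modality. "elementwise" applies the softmax per latent
#'   coordinate across the three z_i (requires equal-length modality
#'   blocks only at the projection level; weights are then averaged to
#'   scalars for the weighted concatenation).
#' @return config list.
#' @export
scrnConfig <- function(d1 = 1024L, d2 = 64L, d3 = 192L, dz = 64L,
                       kernel = 3L, negative_slope = 0.01,
                       gate_mode = c("scalar", "elementwise")) {
  stopifnot(kernel %% 2 == 1, dz >= 1)
  list(d1 = as.integer(d1), d2 = as.integer(d2), d3 = as.integer(d3),
       dz = as.integer(dz), kernel = as.integer(kernel),
       negative_slope = negative_slope, gate_mode = match.arg(gate_mode))
}

#' Initialize SCRN parameters (seeded Glorot)
#' @param cfg a \code{\link{scrnConfig}}.
#' @param seed RNG seed.
#' @return parameter list.
#' @export
initScrn <- function(cfg = scrnConfig(), seed = 0L) {
  withSeed(seed, {
    list(cfg = cfg,
         proj = list(
           W1 = xavierMatrix(cfg$dz, cfg$d1), b1 = numeric(cfg$dz),
           W2 = xavierMatrix(cfg$dz, cfg$d2), b2 = numeric(cfg$dz),
           W3 = xavierMatrix(cfg$dz, cfg$d3), b3 = numeric(cfg$dz)),
         ## gate projections start at zero: uniform (1/3) gates at
         ## init; joint training moves them off the symmetric point
         gate = list(u1 = numeric(cfg$dz), c1 = 0,
                     u2 = numeric(cfg$dz), c2 = 0,
                     u3 = numeric(cfg$dz), c3 = 0),
         ## second conv zero-initialized: the residual branch starts as
         ## an exact pass-through (y = X), standard for residual blocks
         conv = list(w1 = as.vector(xavierMatrix(1, cfg$kernel)), cb1 = 0,
                     w2 = numeric(cfg$kernel), cb2 = 0),
         seed = as.integer(seed))
  })
}

bundleDims <- function(b) c(length(b@x1), length(b@x2), length(b@x3))

checkBundle <- function(b, cfg) {
  d <- bundleDims(b)
  if (!all(d == c(cfg$d1, cfg$d2, cfg$d3)))
    stopMv("ShapeError",
           "bundle dims %s do not match config (%d, %d, %d)",
           paste(d, collapse = ","), cfg$d1, cfg$d2, cfg$d3)
  invisible(TRUE)
}

#' Project the three modalities into the shared latent space
#'
#' z_i = W_i x_i + b_i, all of length dz.
#'
#' @param b a \linkS4class{ModalityBundle}.
#' @param model SCRN parameters from \code{\link{initScrn}}.
#' @return list(z1, z2, z3).
#' @export
projectModalities <- function(b, model) {
  checkBundle(b, model$cfg)
  p <- model$proj
  list(z1 = as.vector(p$W1 %*% b@x1 + p$b1),
       z2 = as.vector(p$W2 %*% b@x2 + p$b2),
       z3 = as.vector(p$W3 %*% b@x3 + p$b3))
}

#' Modality gate weights
#'
#' Each projected latent is reduced to a scalar logit by a learned
#' projection; softmax over the three logits gives strictly positive
#' weights summing to one (shift-invariant in the logits).
#'
#' @param z list(z1, z2, z3) from \code{\link{projectModalities}}.
#' @param model SCRN parameters.
#' @return list(logits, weights), both length 3.
#' @export
gateWeights <- function(z, model) {
  g <- model$gate
  logits <- c(sum(g$u1 * z$z1) + g$c1,
              sum(g$u2 * z$z2) + g$c2,
              sum(g$u3 * z$z3) + g$c3)
  if (!all(is.finite(logits)))
    stopMv("NumericsError", "non-finite gate logits")
  list(logits = logits, weights = softmax(logits))
}

#' Gated concatenation of the original modality vectors
#'
#' X = [w1 x1; w2 x2; w3 x3] (the original inputs are scaled, not the
#' projections).
#'
#' @param b a \linkS4class{ModalityBundle}.
#' @param w gate weights (list from \code{\link{gateWeights}} or a
#'   numeric length-3 vector).
#' @return numeric vector of length d1 + d2 + d3.
#' @export
fuseModalities <- function(b, w) {
  wv <- if (is.list(w)) w$weights else w
  stopifnot(length(wv) == 3)
  c(wv[1] * b@x1, wv[2] * b@x2, wv[3] * b@x3)
}

## 1D same-padding correlation with a length-K (odd) kernel.
conv1dSame <- function(x, w, b) {
  K <- length(w); half <- (K - 1L) / 2L
  n <- length(x)
  y <- rep(b, n)
  for (j in seq_len(K)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    y[ok] <- y[ok] + w[j] * x[src[ok]]
  }
  y
}

## Gradient helpers for the same correlation.
conv1dSameBackData <- function(dz, w) {
  K <- length(w); half <- (K - 1L) / 2L
  n <- length(dz)
  dx <- numeric(n)
  for (j in seq_len(K)) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    dx[src[ok]] <- dx[src[ok]] + w[j] * dz[ok]
  }
  dx
}

conv1dSameBackW <- function(dz, x, K) {
  half <- (K - 1L) / 2L
  n <- length(x)
  vapply(seq_len(K), function(j) {
    off <- j - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    sum(dz[ok] * x[src[ok]])
  }, numeric(1))
}

#' Residual 1D convolutional refinement
#'
#' h1 = f1(w1 * X + b1); h2 = f2(w2 * h1 + b2); y = h2 + X, with
#' length-preserving (same-padding, single-channel) convolutions and
#' LeakyReLU activations, so y has exactly the length of X. With zeroed
#' refinement weights this is the identity.
#'
#' @param X fused vector from \code{\link{fuseModalities}}.
#' @param model SCRN parameters.
#' @return refined drug embedding y, same length as X.
#' @export
residualRefine <- function(X, model) {
  cfg <- model$cfg; cv <- model$conv
  z1 <- conv1dSame(X, cv$w1, cv$cb1)
  h1 <- leakyRelu(z1, cfg$negative_slope)
  z2 <- conv1dSame(h1, cv$w2, cv$cb2)
  h2 <- leakyRelu(z2, cfg$negative_slope)
  h2 + X
}

#' Full SCRN forward pass
#'
#' @param b a \linkS4class{ModalityBundle}.
#' @param model SCRN parameters.
#' @param keep keep intermediate activations for backprop.
#' @return list(y, weights, logits, X, z [, cache]).
#' @export
scrnForward <- function(b, model, keep = FALSE) {
  z <- projectModalities(b, model)
  gw <- gateWeights(z, model)
  X <- fuseModalities(b, gw)
  cfg <- model$cfg; cv <- model$conv
  c1 <- conv1dSame(X, cv$w1, cv$cb1)
  h1 <- leakyRelu(c1, cfg$negative_slope)
  c2 <- conv1dSame(h1, cv$w2, cv$cb2)
  h2 <- leakyRelu(c2, cfg$negative_slope)
  y <- h2 + X
  out <- list(y = y, weights = gw$weights, logits = gw$logits, X = X, z = z)
  if (keep) out$cache <- list(b = b, z = z, gw = gw, X = X, c1 = c1,
                              h1 = h1, c2 = c2)
  out
}

## Backprop dL/dy to SCRN parameter gradients (and optionally the
## modality bundle). Used when fusion is trained jointly with the GCN.
scrnBackwardInternal <- function(dy, model, cache) {
  cfg <- model$cfg; cv <- model$conv
  dh2 <- dy
  dc2 <- dh2 * leakyReluGrad(cache$c2, cfg$negative_slope)
  gw2 <- conv1dSameBackW(dc2, cache$h1, cfg$kernel)
  gb2 <- sum(dc2)
  dh1 <- conv1dSameBackData(dc2, cv$w2)
  dc1 <- dh1 * leakyReluGrad(cache$c1, cfg$negative_slope)
  gw1 <- conv1dSameBackW(dc1, cache$X, cfg$kernel)
  gb1 <- sum(dc1)
  dX <- dy + conv1dSameBackData(dc1, cv$w1)
  ## split dX over the three blocks
  b <- cache$b
  d1 <- length(b@x1); d2 <- length(b@x2); d3 <- length(b@x3)
  seg <- list(seq_len(d1), d1 + seq_len(d2), d1 + d2 + seq_len(d3))
  xs <- list(b@x1, b@x2, b@x3)
  w <- cache$gw$weights
  dw <- vapply(1:3, function(i) sum(dX[seg[[i]]] * xs[[i]]), numeric(1))
  ## softmax backward
  dlog <- w * (dw - sum(w * dw))
  g <- model$gate
  us <- list(g$u1, g$u2, g$u3)
  dz <- lapply(1:3, function(i) dlog[i] * us[[i]])
  grads <- list(
    gate = list(u1 = dlog[1] * cache$z$z1, c1 = dlog[1],
                u2 = dlog[2] * cache$z$z2, c2 = dlog[2],
                u3 = dlog[3] * cache$z$z3, c3 = dlog[3]),
    proj = list(W1 = outer(dz[[1]], b@x1), b1 = dz[[1]],
                W2 = outer(dz[[2]], b@x2), b2 = dz[[2]],
                W3 = outer(dz[[3]], b@x3), b3 = dz[[3]]),
    conv = list(w1 = gw1, cb1 = gb1, w2 = gw2, cb2 = gb2))
  ## gradient w.r.t. the modality vectors (for upstream fine-tuning)
  grads$dx <- lapply(1:3, function(i)
    w[i] * dX[seg[[i]]] + as.vector(crossprod(model$proj[[paste0("W", i)]],
                                              dz[[i]])))
  grads
}
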