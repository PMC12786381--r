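## Interpretability: Grad-CAM over the six views, modality gate-weight
## reports, and the orphan-entity evaluation protocol.

#' Linear Grad-CAM head over the global latent
#'
#' Packages a scalar model output s = f(v) of the encoder latent with
#' its gradient, for use by \code{\link{gradCam}} and the occlusion
#' helpers. \code{gradcamLinearHead} builds the common linear case
#' s = <w, v>.
#'
#' @param w weight vector of length latent_dim.
#' @return list(value = function(v), grad = function(v)).
#' @export
gradcamLinearHead <- function(w) {
  force(w)
  list(value = function(v) sum(w * v), grad = function(v) w)
}

#' Grad-CAM heatmaps over the six views
#'
#' Computes, for a chosen encoder convolution layer, the gradient of a
#' scalar model output with respect to the layer's activations;
#' channel weights are the per-view spatial means of that gradient,
#' and the heatmap is the rectified, weight-averaged activation map,
#' upsampled to H x W and normalized to [0, 1] per view (an all-zero
#' map stays zero).
#'
#' @param model spatial autoencoder parameters.
#' @param t a \linkS4class{ViewTensor} (or 4 x 6 x H x W array).
#' @param head scalar head, e.g. \code{\link{gradcamLinearHead}}.
#' @param target_layer encoder conv layer index (1-based).
#' @return 6 x H x W array of per-view heatmaps in [0, 1].
#' @export
gradCam <- function(model, t, head, target_layer = 2L) {
  x <- asViewArray(t)
  checkViewShape(x, model$cfg)
  nl <- length(model$enc)
  if (!is.numeric(target_layer) || target_layer < 1 || target_layer > nl)
    stopMv("ConfigError",
           "target_layer must index an encoder conv layer (1..%d)", nl)
  cfg <- model$cfg
  fw <- encodeForwardInternal(x, model, keep = TRUE)
  dv <- head$grad(fw$v)
  ## backprop dv down to the post-activation of the target layer
  dflat <- as.vector(crossprod(model$to_latent$W, dv))
  dh <- array(dflat, dim(fw$cache$pre[[nl]]))
  for (k in rev(seq_len(nl))) {
    if (k == target_layer) break
    dz <- dh * leakyReluGrad(fw$cache$pre[[k]], cfg$negative_slope)
    dh <- convBackwardData(dz, model$enc[[k]]$W, fw$cache$geoms$geoms[[k]])
  }
  A <- leakyRelu(fw$cache$pre[[target_layer]], cfg$negative_slope)
  d <- dim(A)   # channels x 6 x h x w
  H <- cfg$H; W <- cfg$W
  cams <- array(0, c(6, H, W))
  for (vw in seq_len(6)) {
    alpha <- apply(dh[, vw, , , drop = FALSE], 1, mean)   # per channel
    cam <- apply(A[, vw, , , drop = FALSE] *
                   array(alpha, dim(A[, vw, , , drop = FALSE])),
                 c(3, 4), sum)
    cam <- pmax(cam, 0)
    ## nearest-neighbour upsample h x w -> H x W
    ri <- ceiling(seq_len(H) / (H / nrow(cam)))
    ci <- ceiling(seq_len(W) / (W / ncol(cam)))
    up <- cam[ri, ci, drop = FALSE]
    mx <- max(up)
    cams[vw, , ] <- if (mx > 0) up / mx else up
  }
  cams
}

#' Mask pixels of a view tensor
#'
#' Sets all four channels to zero at the selected pixels of every view:
#' either the top fraction by Grad-CAM saliency (per view) or a
#' seeded uniformly random fraction.
#'
#' @param t a \linkS4class{ViewTensor} or array.
#' @param frac fraction of pixels masked per view.
#' @param cams 6 x H x W saliency maps (required for mode "top").
#' @param mode "top" or "random".
#' @param seed RNG seed for mode "random".
#' @return masked 4 x 6 x H x W array.
#' @export
maskViewPixels <- function(t, frac = 0.1, cams = NULL,
                           mode = c("top", "random"), seed = 0L) {
  mode <- match.arg(mode)
  x <- asViewArray(t)
  d <- dim(x)
  npix <- d[3] * d[4]
  nmask <- max(1, round(frac * npix))
  withSeed(if (mode == "random") seed else NULL, {
    for (vw in seq_len(6)) {
      sel <- if (mode == "top") {
        stopifnot(!is.null(cams))
        order(cams[vw, , ], decreasing = TRUE)[seq_len(nmask)]
      } else sample(npix, nmask)
      rows <- ((sel - 1) %% d[3]) + 1
      cols <- ((sel - 1) %/% d[3]) + 1
      for (p in seq_along(sel)) x[, vw, rows[p], cols[p]] <- 0
    }
    x
  })
}

#' Occlusion sanity delta for Grad-CAM
#'
#' |s(masked) - s(original)| of the scalar head after masking the top
#' \code{frac} salient pixels versus a random \code{frac}. Because the
#' canvas is mostly empty (zeroing an already-zero background pixel is a
#' no-op), the saliency ranking is restricted to occupied pixels
#' (alpha > 0) before the top set is chosen; the first encoder layer is
#' the default target since its maps are least blurred by striding.
#'
#' @param model spatial autoencoder parameters.
#' @param t view tensor.
#' @param head scalar head (see \code{\link{gradcamLinearHead}}).
#' @param target_layer encoder layer for the saliency maps.
#' @param frac masked fraction.
#' @param seed seed for the random mask.
#' @return list(top, random): absolute score changes.
#' @export
occlusionDeltas <- function(model, t, head, target_layer = 1L,
                            frac = 0.1, seed = 0L) {
  x <- asViewArray(t)
  s0 <- head$value(encodeGlobal(x, model))
  cams <- gradCam(model, x, head, target_layer)
  for (vw in seq_len(6))
    cams[vw, , ] <- cams[vw, , ] * (x[4, vw, , ] > 0)
  xt <- maskViewPixels(x, frac, cams, "top")
  xr <- maskViewPixels(x, frac, mode = "random", seed = seed)
  list(top = abs(head$value(encodeGlobal(xt, model)) - s0),
       random = abs(head$value(encodeGlobal(xr, model)) - s0))
}

#' Mean modality gate weights over a molecule set
#'
#' Per-molecule SCRN gate weights and their means (which sum to one);
#' the per-task means correspond to the modality contribution
#' percentages reported for fused models.
#'
#' @param model SCRN parameters.
#' @param bundles list of \linkS4class{ModalityBundle}s.
#' @return list(per_molecule = n x 3 matrix, mean = length-3 vector).
#' @export
modalityWeightReport <- function(model, bundles) {
  W <- t(vapply(bundles, function(b)
    scrnForward(b, model)$weights, numeric(3)))
  rownames(W) <- vapply(bundles, molId, character(1))
  colnames(W) <- c("fingerprint", "graph", "spatial")
  list(per_molecule = W, mean = colMeans(W))
}

#' Orphan-entity evaluation protocol
#'
#' Removes every edge incident to one entity from the training
#' adjacency and labels (the node and its features are kept), trains
#' the link predictor on the pruned graph, and evaluates on the
#' entity's true positives plus an equal number of seeded random
#' negatives (1:1), returned ranked by predicted score.
#'
#' @param graph full \linkS4class{InteractionGraph}.
#' @param entity_id a drug or partner id present in the graph.
#' @param seed RNG seed (pruned training + negative draw).
#' @param cfg a \code{\link{gcnConfig}}.
#' @return list(train_graph, eval_set, ranked): the pruned graph, the
#'   balanced evaluation pairs and a data.frame ranked by score.
#' @export
orphanEntityProtocol <- function(graph, entity_id, seed = 0L,
                                 cfg = gcnConfig()) {
  isDrug <- entity_id %in% graph@drugIds
  isPartner <- entity_id %in% graph@partnerIds
  if (!isDrug && !isPartner)
    stopMv("KeyError", "unknown entity '%s'", entity_id)
  n <- length(graph@drugIds)
  node <- if (isDrug) match(entity_id, graph@drugIds)
          else n + match(entity_id, graph@partnerIds)
  if (graph@task == "ddi" && isPartner && !isDrug)
    node <- match(entity_id, graph@partnerIds)
  ## positives of the entity in the FULL graph
  if (isDrug) {
    posIdx <- which(graph@labels[match(entity_id, graph@drugIds), ] > 0)
    if (length(posIdx) == 0)
      stopMv("InputError", "entity '%s' has no positives", entity_id)
  } else {
    posIdx <- which(graph@labels[, match(entity_id, graph@partnerIds)] > 0)
    if (length(posIdx) == 0)
      stopMv("InputError", "entity '%s' has no positives", entity_id)
  }
  train <- graph
  A <- train@adjacency
  A[node, ] <- 0; A[, node] <- 0
  train@adjacency <- Matrix::drop0(A)
  Y <- train@labels
  if (isDrug) Y[match(entity_id, graph@drugIds), ] <- 0
  if (isPartner && graph@task != "ddi")
    Y[, match(entity_id, graph@partnerIds)] <- 0
  if (graph@task == "ddi") {
    Y[match(entity_id, graph@drugIds), ] <- 0
    Y[, match(entity_id, graph@drugIds)] <- 0
  }
  train@labels <- Y
  withSeed(seed, {
    ## balanced eval set: all positives + equal-count random negatives
    if (isDrug) {
      di <- match(entity_id, graph@drugIds)
      negPool <- which(graph@labels[di, ] == 0)
      if (graph@task == "ddi") negPool <- setdiff(negPool, di)
    } else {
      pi_ <- match(entity_id, graph@partnerIds)
      negPool <- which(graph@labels[, pi_] == 0)
    }
    if (length(negPool) < length(posIdx)) {
      message(sprintf(
        "entity '%s': only %d unobserved pairs; subsampling positives",
        entity_id, length(negPool)))
      posIdx <- sort(sample(posIdx, length(negPool)))
    }
    negIdx <- sample(negPool, length(posIdx))
    evalSet <- if (isDrug)
      data.frame(i = di, j = c(posIdx, negIdx),
                 label = rep(c(1L, 0L), each = length(posIdx)))
    else
      data.frame(i = c(posIdx, negIdx), j = pi_,
                 label = rep(c(1L, 0L), each = length(posIdx)))
    fit <- trainLinkPredictor(train, cfg, seed = seed)
    S <- linkScores(fit, train)
    evalSet$score <- S[cbind(evalSet$i, evalSet$j)]
    ranked <- evalSet[order(-evalSet$score), ]
    ranked$rank <- seq_len(nrow(ranked))
    list(train_graph = train, eval_set = evalSet, ranked = ranked)
  })
}
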