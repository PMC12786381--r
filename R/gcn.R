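## Heterogeneous interaction graph + symmetric-normalized GCN link
## predictor, trained with binary cross-entropy under 1:1 negative
## sampling; plus the scalar-property regression head.

#' Build an interaction graph from embeddings and positive pairs
#'
#' Bipartite for drug-target ("dti") and drug-miRNA ("dmi"); unipartite
#' over the drug set for drug-drug ("ddi"). The adjacency contains the
#' known positive pairs as symmetric edges (no self-loops; those are
#' added only inside the GCN normalization). Node features use the block
#' layout: drug rows carry the drug embedding in the first fd columns,
#' partner rows the partner embedding in the last ft columns.
#'
#' @param drugEmb n x fd matrix with drug ids as rownames.
#' @param partnerEmb m x ft matrix with partner ids as rownames (ignored
#'   for "ddi", where partners are the drugs).
#' @param positives data.frame with columns drug, partner (ids).
#' @param task "dti", "ddi" or "dmi".
#' @return an \linkS4class{InteractionGraph}.
#' @export
buildInteractionGraph <- function(drugEmb, partnerEmb = NULL, positives,
                                  task = c("dti", "ddi", "dmi")) {
  task <- match.arg(task)
  dIds <- rownames(drugEmb)
  stopifnot(!is.null(dIds))
  if (task == "ddi") {
    partnerEmb <- drugEmb
    pIds <- dIds
  } else {
    stopifnot(!is.null(partnerEmb), !is.null(rownames(partnerEmb)))
    pIds <- rownames(partnerEmb)
  }
  n <- length(dIds); m <- length(pIds)
  di <- match(as.character(positives$drug), dIds)
  pj <- match(as.character(positives$partner), pIds)
  if (anyNA(di) || anyNA(pj)) {
    bad <- unique(c(as.character(positives$drug)[is.na(di)],
                    as.character(positives$partner)[is.na(pj)]))
    stopMv("KeyError", "unknown id(s): %s", paste(bad, collapse = ", "))
  }
  if (task == "ddi" && any(di == pj))
    stopMv("InputError", "self-interaction pair(s) rejected for ddi: %s",
           paste(unique(dIds[di[di == pj]]), collapse = ", "))
  key <- paste(di, pj)
  if (anyDuplicated(key)) {
    message(sprintf("deduplicated %d repeated pair(s)",
                    sum(duplicated(key))))
    keep <- !duplicated(key)
    di <- di[keep]; pj <- pj[keep]
  }
  Y <- matrix(0, n, m, dimnames = list(dIds, pIds))
  Y[cbind(di, pj)] <- 1
  if (task == "ddi") {
    Y[cbind(pj, di)] <- 1
    nn <- n
    A <- Matrix::sparseMatrix(i = c(di, pj), j = c(pj, di), x = 1,
                              dims = c(nn, nn), use.last.ij = TRUE)
    feats <- unname(as.matrix(drugEmb))
    fd <- ncol(drugEmb); ft <- 0L
  } else {
    nn <- n + m
    A <- Matrix::sparseMatrix(i = c(di, n + pj), j = c(n + pj, di), x = 1,
                              dims = c(nn, nn), use.last.ij = TRUE)
    fd <- ncol(drugEmb); ft <- ncol(partnerEmb)
    feats <- matrix(0, nn, fd + ft)
    feats[seq_len(n), seq_len(fd)] <- as.matrix(drugEmb)
    feats[n + seq_len(m), fd + seq_len(ft)] <- as.matrix(partnerEmb)
  }
  new("InteractionGraph", task = task, drugIds = dIds, partnerIds = pIds,
      adjacency = Matrix::drop0(A), labels = Y, features = feats,
      fd = as.integer(fd), ft = as.integer(ft))
}

## Symmetric normalization with self-loops: D~^{-1/2} (A + I) D~^{-1/2}.
gcnNormalize <- function(A) {
  At <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(At)
  Dm <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dm %*% At %*% Dm
}

#' One graph-convolution layer
#'
#' H' = LeakyReLU(D~^{-1/2} (A + I) D~^{-1/2} H W), the self-loop
#' symmetric normalization with a leaky rectifier.
#'
#' @param H node features (rows = nodes).
#' @param A symmetric adjacency (no self-loops required; they are added
#'   internally).
#' @param W layer weight matrix (ncol(H) x out_dim).
#' @param negative_slope LeakyReLU slope.
#' @return transformed node features.
#' @export
gcnLayer <- function(H, A, W, negative_slope = 0.01) {
  if (nrow(A) != ncol(A) || max(abs(A - Matrix::t(A))) > 0)
    stopMv("InputError", "adjacency must be square and symmetric")
  if (nrow(H) != nrow(A))
    stopMv("ShapeError", "H rows (%d) must match adjacency dim (%d)",
           nrow(H), nrow(A))
  N <- gcnNormalize(A)
  leakyRelu(as.matrix(N %*% (H %*% W)), negative_slope)
}

#' GCN link-predictor configuration
#'
#' @param hidden hidden dimensions of the L GCN layers. The default is a
#'   single layer (L = 1): on desk-scale graphs deeper nonlinear stacks
#'   measurably overfit and lose held-out AUC, while a single
#'   linear-output propagation layer recovers planted low-rank structure
#'   reliably; pass e.g. \code{c(128L, 128L)} for the deeper stack.
#' @param negative_slope LeakyReLU slope.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param neg_resample draw fresh 1:1 negatives each epoch (default) or
#'   fix one seeded draw per run.
#' @param final_linear leave the last layer unrectified so final
#'   embeddings can carry signed coordinates into the inner product.
#' @param weight_decay L2 penalty on the GCN weights.
#' @param input_dropout dropout rate on the node features during
#'   training (0 disables).
#' @param score "inner" (sigmoid of inner product) or "bilinear"
#'   (sigmoid of x' B t with a trainable B).
#' @return config list.
#' @export
gcnConfig <- function(hidden = 16L, negative_slope = 0.01,
                      lr = 1e-2, epochs = 600L, neg_resample = TRUE,
                      final_linear = TRUE, weight_decay = 1e-3,
                      input_dropout = 0,
                      score = c("inner", "bilinear")) {
  list(hidden = as.integer(hidden), negative_slope = negative_slope,
       lr = lr, epochs = as.integer(epochs),
       neg_resample = isTRUE(neg_resample),
       final_linear = isTRUE(final_linear), weight_decay = weight_decay,
       input_dropout = input_dropout,
       score = match.arg(score))
}

initGcn <- function(in_dim, cfg, seed = 0L) {
  withSeed(seed, {
    dims <- c(in_dim, cfg$hidden)
    Ws <- lapply(seq_along(cfg$hidden), function(l)
      xavierMatrix(dims[l], dims[l + 1], fan_in = dims[l],
                   fan_out = dims[l + 1]))
    B <- if (cfg$score == "bilinear")
      diag(cfg$hidden[length(cfg$hidden)]) else NULL
    list(cfg = cfg, Ws = Ws, B = B, in_dim = in_dim, seed = as.integer(seed))
  })
}

gcnForwardInternal <- function(H0, N, model, keep = FALSE) {
  cfg <- model$cfg
  H <- H0
  cache <- list(inputs = list(), pre = list())
  nL <- length(model$Ws)
  for (l in seq_len(nL)) {
    if (keep) cache$inputs[[l]] <- H
    Z <- as.matrix(N %*% (H %*% model$Ws[[l]]))
    if (keep) cache$pre[[l]] <- Z
    H <- if (l == nL && isTRUE(cfg$final_linear)) Z
         else leakyRelu(Z, cfg$negative_slope)
  }
  list(H = H, cache = cache)
}

gcnBackwardInternal <- function(dH, N, model, cache, want_dH0 = FALSE) {
  cfg <- model$cfg
  grads <- list(Ws = vector("list", length(model$Ws)))
  nL <- length(model$Ws)
  for (l in rev(seq_len(nL))) {
    dZ <- if (l == nL && isTRUE(cfg$final_linear)) dH
          else dH * leakyReluGrad(cache$pre[[l]], cfg$negative_slope)
    NdZ <- as.matrix(Matrix::t(N) %*% dZ)
    grads$Ws[[l]] <- crossprod(cache$inputs[[l]], NdZ)
    if (l > 1 || want_dH0) dH <- NdZ %*% t(model$Ws[[l]])
  }
  if (want_dH0) grads$dH0 <- dH
  grads
}

scorePairsInternal <- function(Hfin, graph, model) {
  n <- length(graph@drugIds)
  X <- Hfin[seq_len(n), , drop = FALSE]
  T_ <- if (graph@task == "ddi") X
        else Hfin[n + seq_len(length(graph@partnerIds)), , drop = FALSE]
  M <- if (!is.null(model$B)) X %*% model$B %*% t(T_) else tcrossprod(X, T_)
  list(logits = M, X = X, T_ = T_)
}

#' Predict interaction probabilities
#'
#' Sigmoid of the inner product (or bilinear form) of the final drug and
#' partner node representations; for "ddi" the score is symmetric.
#'
#' @param Hfin final node representations from the GCN stack.
#' @param graph the \linkS4class{InteractionGraph}.
#' @param model trained link model (for the optional bilinear form);
#'   omit for plain inner-product scoring.
#' @return n x m probability matrix (entries strictly inside (0, 1)),
#'   dimnames = drug/partner ids.
#' @export
predictScores <- function(Hfin, graph, model = list(B = NULL)) {
  sp <- scorePairsInternal(Hfin, graph, model)
  S <- sigmoid(sp$logits)
  dimnames(S) <- list(graph@drugIds, graph@partnerIds)
  S
}

#' Binary cross-entropy over a set of scored pairs
#'
#' Probabilities are clipped to [1e-7, 1 - 1e-7] before the logs.
#'
#' @param Y 0/1 label matrix.
#' @param Yhat probability matrix of the same shape.
#' @param mask logical matrix (same shape) or two-column index matrix
#'   selecting the trained pairs.
#' @return scalar mean BCE over the masked entries.
#' @export
bceLoss <- function(Y, Yhat, mask = NULL) {
  if (!all(dim(Y) == dim(Yhat)))
    stopMv("ShapeError", "Y and Yhat shapes differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(Y), ncol(Y))
  idx <- if (is.logical(mask)) which(mask) else (mask[, 2] - 1) * nrow(Y) +
    mask[, 1]
  if (length(idx) == 0) stopMv("InputError", "empty mask")
  p <- pmin(pmax(Yhat[idx], 1e-7), 1 - 1e-7)
  y <- Y[idx]
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Uniform 1:1 negative sampling from unobserved pairs (labels == 0),
## excluding the diagonal for ddi and any explicitly excluded pairs.
sampleNegativePairs <- function(graph, n_neg, exclude = NULL) {
  Y <- graph@labels
  n <- nrow(Y); m <- ncol(Y)
  forbidden <- Y > 0
  if (graph@task == "ddi") diag(forbidden) <- TRUE
  if (!is.null(exclude))
    forbidden[(exclude[, 2] - 1) * n + exclude[, 1]] <- TRUE
  candidates <- which(!forbidden)
  if (graph@task == "ddi") {
    ut <- which(!forbidden & upper.tri(Y))
    candidates <- ut
  }
  if (length(candidates) == 0)
    stopMv("InputError", "no unobserved pairs to sample negatives from")
  if (length(candidates) < n_neg) {
    message(sprintf("only %d unobserved pairs available for %d negatives",
                    length(candidates), n_neg))
    n_neg <- length(candidates)
  }
  sel <- sample(candidates, n_neg)
  cbind(i = ((sel - 1) %% n) + 1, j = ((sel - 1) %/% n) + 1)
}

#' Train the GCN link predictor
#'
#' Propagates the block node features through L symmetric-normalized GCN
#' layers and trains on binary cross-entropy over the graph's positive
#' pairs plus an equal number of uniformly sampled unobserved pairs
#' (1:1). Only the edges present in \code{graph} enter the propagation
#' adjacency, so held-out test edges must be excluded from the graph by
#' the caller (see \code{\link{edgeSplit}}). Negatives are drawn once per
#' run by default (resampling per epoch behind \code{neg_resample}).
#' Optionally the SCRN fusion parameters are trained jointly via
#' \code{scrn} (a list with elements model and bundles).
#'
#' @param graph training \linkS4class{InteractionGraph}.
#' @param cfg a \code{\link{gcnConfig}}.
#' @param seed RNG seed (init + negative sampling).
#' @param scrn optional list(model, bundles) to fine-tune fusion jointly.
#' @param exclude_pairs optional two-column (i, j) matrix of pairs that
#'   must never be drawn as training negatives (e.g. held-out test
#'   pairs, as is standard in link-prediction benchmarks).
#' @param verbose print loss every 25 epochs.
#' @return list(model, loss, neg_pairs, scrn): trained parameters, the
#'   per-epoch loss trajectory and the sampled negative pairs.
#' @export
trainLinkPredictor <- function(graph, cfg = gcnConfig(), seed = 0L,
                               scrn = NULL, exclude_pairs = NULL,
                               verbose = FALSE) {
  stopifnot(is(graph, "InteractionGraph"))
  pos <- which(graph@labels > 0, arr.ind = TRUE)
  if (graph@task == "ddi") pos <- pos[pos[, 1] < pos[, 2], , drop = FALSE]
  if (nrow(pos) == 0) stopMv("InputError", "graph has no positive pairs")
  N <- gcnNormalize(graph@adjacency)
  model <- initGcn(ncol(graph@features), cfg, seed)
  params <- stats::setNames(model$Ws, paste0("W", seq_along(model$Ws)))
  useScrn <- !is.null(scrn)
  if (useScrn) {
    sm <- scrn$model
    params <- c(params, list(
      s_projW1 = sm$proj$W1, s_projb1 = sm$proj$b1,
      s_projW2 = sm$proj$W2, s_projb2 = sm$proj$b2,
      s_projW3 = sm$proj$W3, s_projb3 = sm$proj$b3,
      s_gu1 = sm$gate$u1, s_gc1 = sm$gate$c1,
      s_gu2 = sm$gate$u2, s_gc2 = sm$gate$c2,
      s_gu3 = sm$gate$u3, s_gc3 = sm$gate$c3,
      s_cw1 = sm$conv$w1, s_cb1 = sm$conv$cb1,
      s_cw2 = sm$conv$w2, s_cb2 = sm$conv$cb2))
  }
  opt <- adamInit(params)
  n <- length(graph@drugIds)
  losses <- numeric(0)
  withSeed(seed + 1L, {
    neg <- sampleNegativePairs(graph, nrow(pos), exclude = exclude_pairs)
    H0 <- graph@features
    for (ep in seq_len(cfg$epochs)) {
      if (cfg$neg_resample && ep > 1)
        neg <- sampleNegativePairs(graph, nrow(pos),
                                   exclude = exclude_pairs)
      if (useScrn) {
        sm <- scrn$model
        sm$proj$W1 <- params$s_projW1; sm$proj$b1 <- params$s_projb1
        sm$proj$W2 <- params$s_projW2; sm$proj$b2 <- params$s_projb2
        sm$proj$W3 <- params$s_projW3; sm$proj$b3 <- params$s_projb3
        sm$gate$u1 <- params$s_gu1; sm$gate$c1 <- params$s_gc1
        sm$gate$u2 <- params$s_gu2; sm$gate$c2 <- params$s_gc2
        sm$gate$u3 <- params$s_gu3; sm$gate$c3 <- params$s_gc3
        sm$conv$w1 <- params$s_cw1; sm$conv$cb1 <- params$s_cb1
        sm$conv$w2 <- params$s_cw2; sm$conv$cb2 <- params$s_cb2
        scrnOut <- lapply(scrn$bundles, scrnForward, model = sm,
                          keep = TRUE)
        for (i in seq_along(scrnOut))
          H0[i, seq_len(graph@fd)] <- scrnOut[[i]]$y
      }
      model$Ws <- params[paste0("W", seq_along(model$Ws))]
      Hin <- H0
      if (cfg$input_dropout > 0) {
        keepMask <- matrix(rbinom(length(H0), 1, 1 - cfg$input_dropout),
                           nrow(H0)) / (1 - cfg$input_dropout)
        Hin <- H0 * keepMask
      }
      fw <- gcnForwardInternal(Hin, N, model, keep = TRUE)
      sp <- scorePairsInternal(fw$H, graph, model)
      P <- sigmoid(sp$logits)
      pairIdx <- rbind(pos, neg)
      yv <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
      pidx <- (pairIdx[, 2] - 1) * n + pairIdx[, 1]
      pv <- pmin(pmax(P[pidx], 1e-7), 1 - 1e-7)
      loss <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
      if (!is.finite(loss))
        stopMv("TrainingDivergedError", "non-finite loss at epoch %d", ep)
      losses <- c(losses, loss)
      ## gradient: dL/dlogit = (p - y)/|mask| at trained pairs
      dM <- matrix(0, nrow(P), ncol(P))
      dM[pidx] <- (pv - yv) / length(yv)
      if (graph@task == "ddi") {
        ## symmetric score: logit(i,j) appears as M[i,j]; propagate both
        dX <- dM %*% sp$T_ + t(dM) %*% sp$X
        dH <- dX
      } else {
        dX <- dM %*% sp$T_
        dT <- t(dM) %*% sp$X
        dH <- rbind(dX, dT)
      }
      grads <- gcnBackwardInternal(dH, N, model, fw$cache,
                                   want_dH0 = useScrn)
      gl <- stats::setNames(grads$Ws, paste0("W", seq_along(grads$Ws)))
      if (cfg$weight_decay > 0)
        for (l in seq_along(model$Ws))
          gl[[l]] <- gl[[l]] + cfg$weight_decay * model$Ws[[l]]
      if (useScrn) {
        acc <- NULL
        for (i in seq_along(scrnOut)) {
          gs <- scrnBackwardInternal(grads$dH0[i, seq_len(graph@fd)], sm,
                                     scrnOut[[i]]$cache)
          flat <- list(
            s_projW1 = gs$proj$W1, s_projb1 = gs$proj$b1,
            s_projW2 = gs$proj$W2, s_projb2 = gs$proj$b2,
            s_projW3 = gs$proj$W3, s_projb3 = gs$proj$b3,
            s_gu1 = gs$gate$u1, s_gc1 = gs$gate$c1,
            s_gu2 = gs$gate$u2, s_gc2 = gs$gate$c2,
            s_gu3 = gs$gate$u3, s_gc3 = gs$gate$c3,
            s_cw1 = gs$conv$w1, s_cb1 = gs$conv$cb1,
            s_cw2 = gs$conv$w2, s_cb2 = gs$conv$cb2)
          acc <- if (is.null(acc)) flat
                 else Map(`+`, acc, flat)
        }
        gl <- c(gl, acc)
      }
      step <- adamStep(params, gl, opt, lr = cfg$lr)
      params <- step$params; opt <- step$state
      if (verbose && ep %% 25 == 0)
        message(sprintf("epoch %d: bce %.4f", ep, loss))
    }
    model$Ws <- params[paste0("W", seq_along(model$Ws))]
    out <- list(model = model, loss = losses, neg_pairs = neg)
    if (useScrn) {
      sm <- scrn$model
      sm$proj$W1 <- params$s_projW1; sm$proj$b1 <- params$s_projb1
      sm$proj$W2 <- params$s_projW2; sm$proj$b2 <- params$s_projb2
      sm$proj$W3 <- params$s_projW3; sm$proj$b3 <- params$s_projb3
      sm$gate$u1 <- params$s_gu1; sm$gate$c1 <- params$s_gc1
      sm$gate$u2 <- params$s_gu2; sm$gate$c2 <- params$s_gc2
      sm$gate$u3 <- params$s_gu3; sm$gate$c3 <- params$s_gc3
      sm$conv$w1 <- params$s_cw1; sm$conv$cb1 <- params$s_cb1
      sm$conv$w2 <- params$s_cw2; sm$conv$cb2 <- params$s_cb2
      out$scrn <- sm
    }
    out
  })
}

#' Score all pairs with a trained link model
#'
#' @param fit result of \code{\link{trainLinkPredictor}}.
#' @param graph the graph to propagate over (training adjacency).
#' @param features optional replacement node features (defaults to the
#'   graph's).
#' @return probability matrix as in \code{\link{predictScores}}.
#' @export
linkScores <- function(fit, graph, features = NULL) {
  H0 <- if (is.null(features)) graph@features else features
  N <- gcnNormalize(graph@adjacency)
  fw <- gcnForwardInternal(H0, N, fit$model)
  predictScores(fw$H, graph, fit$model)
}

#' Split labelled pairs into train/test for link prediction
#'
#' Positives are split at random (seeded); the training graph's
#' adjacency contains only training positives, so test edges never leak
#' into the propagation. Test negatives are sampled 1:1 from pairs
#' unobserved in the FULL graph, excluding training pairs.
#'
#' @param graph full \linkS4class{InteractionGraph}.
#' @param test_frac fraction of positive pairs held out.
#' @param seed RNG seed.
#' @return list(train = graph with reduced edges/labels,
#'   test = data.frame(i, j, label)).
#' @export
edgeSplit <- function(graph, test_frac = 0.2, seed = 0L) {
  stopifnot(test_frac > 0, test_frac < 1)
  pos <- which(graph@labels > 0, arr.ind = TRUE)
  if (graph@task == "ddi") pos <- pos[pos[, 1] < pos[, 2], , drop = FALSE]
  withSeed(seed, {
    nTest <- max(1, round(nrow(pos) * test_frac))
    testSel <- sample(nrow(pos), nTest)
    testPos <- pos[testSel, , drop = FALSE]
    trainPos <- pos[-testSel, , drop = FALSE]
    n <- length(graph@drugIds)
    train <- graph
    Yt <- matrix(0, nrow(graph@labels), ncol(graph@labels),
                 dimnames = dimnames(graph@labels))
    Yt[trainPos] <- 1
    if (graph@task == "ddi") Yt[trainPos[, c(2, 1), drop = FALSE]] <- 1
    train@labels <- Yt
    ii <- trainPos[, 1]; jj <- trainPos[, 2]
    if (graph@task == "ddi") {
      A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                                dims = dim(graph@adjacency),
                                use.last.ij = TRUE)
    } else {
      A <- Matrix::sparseMatrix(i = c(ii, n + jj), j = c(n + jj, ii), x = 1,
                                dims = dim(graph@adjacency),
                                use.last.ij = TRUE)
    }
    train@adjacency <- Matrix::drop0(A)
    ## test negatives: unobserved in the full graph
    testNeg <- sampleNegativePairs(graph, nrow(testPos))
    test <- data.frame(
      i = c(testPos[, 1], testNeg[, 1]),
      j = c(testPos[, 2], testNeg[, 2]),
      label = c(rep(1L, nrow(testPos)), rep(0L, nrow(testNeg))))
    list(train = train, test = test)
  })
}

#' Scalar-property regression head
#'
#' A two-layer feed-forward head on the fused drug embedding, trained
#' with mean-squared error (for LD50-style acute-toxicity endpoints).
#'
#' @param hidden hidden width.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param negative_slope LeakyReLU slope.
#' @return config list.
#' @export
propertyHeadConfig <- function(hidden = 64L, lr = 1e-2, epochs = 400L,
                               negative_slope = 0.01,
                               weight_decay = 0.2) {
  list(hidden = as.integer(hidden), lr = lr, epochs = as.integer(epochs),
       negative_slope = negative_slope, weight_decay = weight_decay)
}

#' Train the property head
#'
#' @param emb n x d matrix of drug embeddings (rownames = ids).
#' @param y numeric endpoint per row.
#' @param cfg a \code{\link{propertyHeadConfig}}.
#' @param seed RNG seed.
#' @return list(head, loss).
#' @export
trainPropertyHead <- function(emb, y, cfg = propertyHeadConfig(),
                              seed = 0L) {
  stopifnot(nrow(emb) == length(y), nrow(emb) >= 2)
  emb <- as.matrix(emb)
  mu <- colMeans(emb); sdv <- apply(emb, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(emb, 2, mu), 2, sdv, "/")
  head <- withSeed(seed, list(
    W1 = xavierMatrix(cfg$hidden, ncol(emb)), b1 = numeric(cfg$hidden),
    W2 = as.vector(xavierMatrix(1, cfg$hidden)), b2 = 0,
    mu = mu, sd = sdv, cfg = cfg))
  params <- head[c("W1", "b1", "W2", "b2")]
  opt <- adamInit(params)
  n <- nrow(Xs)
  losses <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    Z1 <- Xs %*% t(params$W1) + matrix(params$b1, n, cfg$hidden,
                                       byrow = TRUE)
    H1 <- leakyRelu(Z1, cfg$negative_slope)
    pred <- as.vector(H1 %*% params$W2) + params$b2
    resid <- pred - y
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stopMv("TrainingDivergedError", "non-finite loss at epoch %d", ep)
    losses <- c(losses, loss)
    dpred <- 2 * resid / n
    gW2 <- as.vector(crossprod(H1, dpred)); gb2 <- sum(dpred)
    dH1 <- outer(dpred, params$W2)
    dZ1 <- dH1 * leakyReluGrad(Z1, cfg$negative_slope)
    gW1 <- crossprod(dZ1, Xs); gb1 <- colSums(dZ1)
    if (cfg$weight_decay > 0) {
      gW1 <- gW1 + cfg$weight_decay * params$W1
      gW2 <- gW2 + cfg$weight_decay * params$W2
    }
    step <- adamStep(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                     opt, lr = cfg$lr)
    params <- step$params; opt <- step$state
  }
  head[c("W1", "b1", "W2", "b2")] <- params
  list(head = head, loss = losses)
}

#' Predict a scalar property from drug embeddings
#'
#' @param emb embedding matrix (or single vector).
#' @param head trained head from \code{\link{trainPropertyHead}}.
#' @return numeric predictions.
#' @export
predictProperty <- function(emb, head) {
  if (is.null(dim(emb))) emb <- matrix(emb, 1)
  Xs <- sweep(sweep(as.matrix(emb), 2, head$mu), 2, head$sd, "/")
  H1 <- leakyRelu(Xs %*% t(head$W1) +
                    matrix(head$b1, nrow(Xs), length(head$b1), byrow = TRUE),
                  head$cfg$negative_slope)
  as.vector(H1 %*% head$W2) + head$b2
}
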