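## Internal numeric helpers shared across the network modules.

#' @importFrom stats rnorm runif median sd var setNames rbinom
#' @importFrom methods new validObject is slot
#' @importFrom utils head tail read.table write.table
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.  All stochastic code in the
## package funnels through this so that a single integer seed pins a run.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leakyRelu <- function(x, slope = 0.01) pmax(x, slope * x)

leakyReluGrad <- function(x, slope = 0.01) {
  g <- (x > 0) + 0
  g[g == 0] <- slope
  g
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## Glorot/Xavier uniform initialization for a fan_in x fan_out weight.
xavierMatrix <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

stopMv <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "molviewsError", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

## ---- Adam optimizer over a flat named list of numeric arrays ----

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Rank-statistic ROC-AUC with half-credit for ties
## (equals the concordant-pair count / (P*N)).
aucRank <- function(scores, labels) {
  pos <- labels > 0
  P <- sum(pos); Nn <- sum(!pos)
  if (P == 0 || Nn == 0)
    stopMv("UndefinedMetricError", "AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - P * (P + 1) / 2) / (P * Nn)
}

## 32-bit FNV-1a hash in exact double arithmetic (values stay < 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

## Short config fingerprint used to stamp artifacts and manifests.
configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- fnv1a32(s)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
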