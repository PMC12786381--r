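# Interaction graph construction, GCN propagation, scoring, training

toyGraph <- function() {
  dE <- matrix(rnorm(2 * 4), 2, 4,
               dimnames = list(c("d1", "d2"), NULL))
  pE <- matrix(rnorm(3 * 5), 3, 5,
               dimnames = list(c("t1", "t2", "t3"), NULL))
  buildInteractionGraph(dE, pE,
                        data.frame(drug = "d1", partner = "t1"), "dti")
}

test_that("graph construction enforces the block layout and symmetry", {
  set.seed(1)
  g <- toyGraph()
  A <- adjacency(g)
  expect_equal(dim(A), c(5, 5))
  expect_equal(Matrix::nnzero(A), 2)           # one symmetric edge
  expect_equal(max(abs(A - Matrix::t(A))), 0)
  H0 <- nodeFeatures(g)
  expect_true(all(H0[3:5, 1:4] == 0))          # target rows: drug block 0
  expect_true(all(H0[1:2, 5:9] == 0))          # drug rows: target block 0
  expect_error(
    buildInteractionGraph(matrix(1, 2, 2,
                                 dimnames = list(c("d1", "d2"), NULL)),
                          positives = data.frame(drug = "d1",
                                                 partner = "d1"),
                          task = "ddi"),
    class = "InputError")
  expect_error(
    buildInteractionGraph(matrix(1, 2, 2,
                                 dimnames = list(c("d1", "d2"), NULL)),
                          matrix(1, 1, 2, dimnames = list("t1", NULL)),
                          data.frame(drug = "d9", partner = "t1"), "dti"),
    class = "KeyError")
  expect_message(
    buildInteractionGraph(matrix(1, 2, 2,
                                 dimnames = list(c("d1", "d2"), NULL)),
                          matrix(1, 1, 2, dimnames = list("t1", NULL)),
                          data.frame(drug = c("d1", "d1"),
                                     partner = c("t1", "t1")), "dti"),
    "deduplicated")
})

test_that("the normalized operator matches hand and loop oracles", {
  # two nodes, one edge: every entry of the operator is 1/2
  A2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1,
                             dims = c(2, 2))
  expect_true(all(abs(as.matrix(molviews:::gcnNormalize(A2)) - 0.5)
                  < 1e-12))
  # single isolated node: operator is 1, layer = LeakyReLU(h W)
  A1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                             x = numeric(0), dims = c(1, 1))
  h <- matrix(c(-2, 3), 1)
  out <- gcnLayer(h, A1, diag(2), negative_slope = 0.01)
  expect_equal(as.vector(out), c(-0.02, 3))
  # random graphs vs dense construction
  for (s in 1:20) {
    nn <- sample(5:20, 1)
    Am <- randomSymmetricGraph(nn, nn, s)
    H <- matrix(rnorm(nn * 7), nn)
    W <- matrix(rnorm(7 * 4), 7)
    At <- Am + diag(nn)
    D <- diag(1 / sqrt(rowSums(At)))
    Z <- D %*% At %*% D %*% H %*% W
    oracle <- pmax(Z, 0.01 * Z)
    fast <- gcnLayer(H, Matrix::Matrix(Am, sparse = TRUE), W)
    expect_lt(max(abs(fast - oracle)), 1e-6)
    # the normalized operator is a contraction (largest eigenvalue <= 1)
    N <- as.matrix(molviews:::gcnNormalize(Matrix::Matrix(Am,
                                                          sparse = TRUE)))
    expect_lte(max(eigen(N, symmetric = TRUE,
                         only.values = TRUE)$values), 1 + 1e-9)
  }
  expect_error(gcnLayer(matrix(0, 2, 2),
                        Matrix::sparseMatrix(i = 1, j = 2, x = 1,
                                             dims = c(2, 2)),
                        diag(2)),
               class = "InputError")
})

test_that("scores are probabilities; ddi scoring is symmetric", {
  set.seed(2)
  Hfin <- matrix(rnorm(5 * 3), 5)
  g <- toyGraph()
  S <- predictScores(Hfin, g)
  expect_true(all(S > 0 & S < 1))
  zero <- predictScores(matrix(0, 5, 3), g)
  expect_true(all(zero == 0.5))
  dE <- matrix(rnorm(4 * 6), 4, 6,
               dimnames = list(paste0("d", 1:4), NULL))
  gd <- buildInteractionGraph(dE,
                              positives = data.frame(drug = "d1",
                                                     partner = "d2"),
                              task = "ddi")
  Sd <- predictScores(matrix(rnorm(4 * 3), 4), gd)
  expect_lt(max(abs(Sd - t(Sd))), 1e-9)
})

test_that("BCE matches analytic and hand values and validates input", {
  Y <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(bceLoss(Y, matrix(0.5, 2, 2)), log(2), tolerance = 1e-12)
  Yh <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  expect_equal(bceLoss(Y, Yh), -mean(log(c(0.9, 0.8, 0.9, 0.8))),
               tolerance = 1e-9)
  expect_lt(bceLoss(Y, Y), 1e-6)     # perfect fit after clipping
  expect_error(bceLoss(Y, Yh, mask = matrix(FALSE, 2, 2)),
               class = "InputError")
  expect_error(bceLoss(Y, matrix(0.5, 3, 2)), class = "ShapeError")
})

test_that("link training is seeded-deterministic and rejects empty graphs", {
  set.seed(4)
  dE <- matrix(rnorm(6 * 8), 6, 8,
               dimnames = list(paste0("d", 1:6), NULL))
  pE <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(paste0("t", 1:5), NULL))
  pos <- data.frame(drug = c("d1", "d2", "d3", "d4"),
                    partner = c("t1", "t2", "t3", "t1"))
  g <- buildInteractionGraph(dE, pE, pos, "dti")
  cfg <- gcnConfig(epochs = 30L)
  f1 <- trainLinkPredictor(g, cfg, seed = 9)
  f2 <- trainLinkPredictor(g, cfg, seed = 9)
  expect_identical(f1$loss, f2$loss)
  expect_identical(f1$neg_pairs, f2$neg_pairs)
  expect_true(all(is.finite(f1$loss)))
  empty <- buildInteractionGraph(dE, pE, pos[0, ], "dti")
  expect_error(trainLinkPredictor(empty, cfg), class = "InputError")
})

test_that("training loss decreases over the first 10 epochs on fixtures", {
  pp <- plantedPipeline()
  sp <- edgeSplit(pp$graph, 0.2, seed = 0)
  fit <- trainLinkPredictor(sp$train, gcnConfig(epochs = 12L), seed = 0)
  expect_lt(fit$loss[11], fit$loss[1])
})

test_that("edge split keeps test positives out of the adjacency", {
  pp <- plantedPipeline()
  for (s in 1:5) {
    sp <- edgeSplit(pp$graph, 0.2, seed = s)
    testPos <- sp$test[sp$test$label == 1, ]
    n <- length(drugIds(pp$graph))
    A <- adjacency(sp$train)
    leaked <- sum(A[cbind(testPos$i, n + testPos$j)])
    expect_equal(leaked, 0)
    # and training labels exclude them too
    expect_true(all(interactionLabels(sp$train)[
      cbind(testPos$i, testPos$j)] == 0))
  }
})

test_that("property head recovers a linear endpoint and degenerates
           gracefully", {
  set.seed(6)
  X <- matrix(rnorm(60 * 10), 60)
  rownames(X) <- paste0("m", 1:60)
  y <- 2 + X %*% c(1, -2, 0.5, rep(0, 7))
  fit <- trainPropertyHead(X[1:45, ], y[1:45], seed = 1)
  pred <- predictProperty(X[46:60, ], fit$head)
  expect_gt(regressionMetrics(y[46:60], pred)$r2, 0.8)
  # zero weights + bias c predict the constant c
  h0 <- fit$head
  h0$W1[] <- 0; h0$b1[] <- 0; h0$W2[] <- 0; h0$b2 <- 3.3
  expect_equal(predictProperty(X[1:5, ], h0), rep(3.3, 5))
})
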