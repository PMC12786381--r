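# Spatial autoencoder: shapes, oracles, grouping, directional paths

test_that("conv3d primitives match the loop oracle and are adjoint", {
  set.seed(1)
  g <- molviews:::convGeom(c(3, 4, 8, 8), c(3, 3, 3), c(1, 2, 2),
                           c(1, 1, 1))
  x <- array(rnorm(prod(g$in_shape)), g$in_shape)
  p <- molviews:::convInit(3, 5, c(3, 3, 3))
  fast <- molviews:::convForward(x, p$W, p$b, g)
  slow <- molviews:::convForwardNaive(x, p$W, p$b, g)
  expect_lt(max(abs(fast - slow)), 1e-10)
  # transposed convolution is the adjoint of the convolution
  u <- array(rnorm(5 * prod(g$out_spatial)), c(5, g$out_spatial))
  lhs <- sum(molviews:::convForward(x, p$W, numeric(5), g) * u)
  rhs <- sum(x * molviews:::tconvForward(u, p$W, numeric(3), g))
  expect_lt(abs(lhs - rhs), 1e-8)
})

test_that("encoder/decoder obey shape, range and determinism contracts", {
  cfg <- spatialConfig(H = 32, W = 32)
  model <- initSpatialAutoencoder(cfg, seed = 0)
  x <- array(runif(4 * 6 * 32 * 32), c(4, 6, 32, 32))
  v <- encodeGlobal(x, model)
  expect_length(v, 128)
  expect_identical(v, encodeGlobal(x, model))
  y <- decodeViews(v, model)
  expect_equal(dim(y), c(4, 6, 32, 32))
  expect_true(all(y >= 0 & y <= 1))      # sigmoid bound
  expect_identical(y, decodeViews(v, model))
  expect_error(encodeGlobal(array(0, c(4, 5, 32, 32)), model),
               class = "ShapeError")
  # distinct fixture molecules embed at distinct latents even untrained
  fz <- featurized20()
  cfg64 <- spatialConfig()
  m64 <- initSpatialAutoencoder(cfg64, seed = 0)
  v1 <- encodeGlobal(fz$tensors[[3]], m64)
  v2 <- encodeGlobal(fz$tensors[[4]], m64)
  expect_gt(sqrt(sum((v1 - v2)^2)), 0)
})

test_that("all-zero decoder weights with zero latent give constant 0.5", {
  cfg <- spatialConfig(H = 32, W = 32)
  model <- initSpatialAutoencoder(cfg, seed = 0)
  model$from_latent$W[] <- 0; model$from_latent$b[] <- 0
  for (k in seq_along(model$dec)) {
    model$dec[[k]]$W[] <- 0; model$dec[[k]]$b[] <- 0
  }
  y <- decodeViews(numeric(128), model)
  expect_true(all(abs(y - 0.5) < 1e-12))   # sigmoid(0)
})

test_that("reconstruction loss equals the elementwise oracle", {
  ones <- array(1, c(4, 6, 2, 2)); zeros <- array(0, c(4, 6, 2, 2))
  expect_equal(reconstructionLoss(ones, zeros), 96)
  expect_equal(reconstructionLoss(ones, ones), 0)
  set.seed(2)
  ys <- lapply(1:3, function(i) array(rnorm(4 * 6 * 4 * 4), c(4, 6, 4, 4)))
  yh <- lapply(1:3, function(i) array(rnorm(4 * 6 * 4 * 4), c(4, 6, 4, 4)))
  oracle <- 0
  for (i in 1:3) {
    s <- 0
    for (j in seq_along(ys[[i]])) s <- s + (ys[[i]][j] - yh[[i]][j])^2
    oracle <- oracle + s
  }
  expect_equal(reconstructionLoss(ys, yh), oracle / 3, tolerance = 1e-6)
  expect_error(reconstructionLoss(list(ones), list(ones, zeros)),
               class = "ShapeError")
})

test_that("view grouping partitions the six views into the fixed pairs", {
  lab <- array(0, c(4, 6, 8, 8))
  for (v in 1:6) lab[, v, , ] <- v / 10
  g <- groupViews(lab)
  expect_equal(dim(g$g1), c(4, 2, 8, 8))
  expect_true(all(g$g2[, 1, , ] == 0.3))   # back
  expect_true(all(g$g2[, 2, , ] == 0.4))   # bottom
  expect_true(all(g$g3[, 1, , ] == 0.5))   # top
  expect_true(all(g$g3[, 2, , ] == 0.6))   # left
  idx <- attr(g, "view_indices")
  expect_setequal(unlist(idx), 1:6)
  expect_error(groupViews(array(0, c(4, 5, 8, 8))), class = "ShapeError")
})

test_that("directional paths are independent and not weight-tied", {
  cfg <- spatialConfig(H = 32, W = 32)
  model <- initSpatialAutoencoder(cfg, seed = 3)
  x <- array(runif(4 * 6 * 32 * 32), c(4, 6, 32, 32))
  g <- groupViews(x)
  base <- directionalEncode(g, model)
  expect_length(base, directionalDim(cfg))
  d3each <- directionalDim(cfg) / 3
  # zeroing path 1 changes only a1 (bias-only output)
  m0 <- model
  for (k in seq_along(m0$dirs[[1]])) m0$dirs[[1]][[k]]$W[] <- 0
  z <- directionalEncode(g, m0)
  expect_false(isTRUE(all.equal(z[1:d3each], base[1:d3each])))
  expect_equal(z[(d3each + 1):(3 * d3each)],
               base[(d3each + 1):(3 * d3each)])
  # swapping g1 and g3 changes x3 (no weight sharing across paths)
  swapped <- directionalEncode(list(g1 = g$g3, g2 = g$g2, g3 = g$g1),
                               model)
  expect_gt(max(abs(swapped - base)), 0)
})

test_that("a short training run decreases loss deterministically", {
  cfg <- spatialConfig(H = 32, W = 32)
  set.seed(11)
  ds <- lapply(1:4, function(i) {
    a <- array(0, c(4, 6, 32, 32))
    a[4, , 8:24, 8:24] <- runif(1)
    a
  })
  tr1 <- trainAutoencoder(ds, cfg, epochs = 8, seed = 5)
  expect_lt(tail(tr1$loss, 1), tr1$loss[1])
  expect_true(all(is.finite(tr1$loss)))
  tr2 <- trainAutoencoder(ds, cfg, epochs = 8, seed = 5)
  expect_identical(tr1$loss, tr2$loss)
  expect_error(trainAutoencoder(ds[1], cfg), class = "InputError")
})
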