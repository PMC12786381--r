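# SCRN fusion: projections, gates, weighted concatenation, refinement

smallBundle <- function(seed = 1, d = c(8, 6, 4)) {
  set.seed(seed)
  new("ModalityBundle", id = "b", x1 = rnorm(d[1]), x2 = rnorm(d[2]),
      x3 = rnorm(d[3]))
}

smallScrn <- function(seed = 3)
  initScrn(scrnConfig(d1 = 8L, d2 = 6L, d3 = 4L, dz = 5L), seed)

test_that("modality projections are affine maps into the shared space", {
  m <- smallScrn(); b <- smallBundle()
  z <- projectModalities(b, m)
  expect_true(all(lengths(z) == 5))
  # zero weights + bias c give the constant c
  m0 <- m
  m0$proj$W1[] <- 0; m0$proj$b1[] <- 0.7
  expect_equal(projectModalities(b, m0)$z1, rep(0.7, 5))
  # linearity around zero
  z0 <- projectModalities(
    new("ModalityBundle", id = "z", x1 = numeric(8), x2 = numeric(6),
        x3 = numeric(4)), m)
  b2 <- b; b2@x1 <- 2 * b@x1; b2@x2 <- 2 * b@x2; b2@x3 <- 2 * b@x3
  z2 <- projectModalities(b2, m)
  for (i in 1:3)
    expect_lt(max(abs((z2[[i]] - z0[[i]]) - 2 * (z[[i]] - z0[[i]]))), 1e-6)
  bad <- new("ModalityBundle", id = "w", x1 = rnorm(3), x2 = rnorm(6),
             x3 = rnorm(4))
  expect_error(projectModalities(bad, m), class = "ShapeError")
})

test_that("gate weights form a shift-invariant probability vector", {
  g1 <- list(gate = list(u1 = 1, c1 = 0, u2 = 1, c2 = 0, u3 = 1, c3 = 0))
  eq <- gateWeights(list(z1 = 0, z2 = 0, z3 = 0), g1)
  expect_equal(eq$weights, rep(1 / 3, 3))
  # scalar softmax oracle at logits (10, 0, 0)
  w <- gateWeights(list(z1 = 10, z2 = 0, z3 = 0), g1)$weights
  expect_equal(w[1], exp(10) / (exp(10) + 2), tolerance = 1e-9)
  # adding a constant to all logits leaves weights unchanged
  shifted <- gateWeights(list(z1 = 10 + 5, z2 = 5, z3 = 5), g1)$weights
  expect_lt(max(abs(shifted - w)), 1e-9)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  # monotonicity: raising one logit raises its weight, lowers the others
  w2 <- gateWeights(list(z1 = 11, z2 = 0, z3 = 0), g1)$weights
  expect_gt(w2[1], w[1]); expect_lt(w2[2], w[2]); expect_lt(w2[3], w[3])
  expect_error(gateWeights(list(z1 = Inf, z2 = 0, z3 = 0), g1),
               class = "NumericsError")
})

test_that("fusion scales the original vectors and concatenates", {
  b <- smallBundle()
  X <- fuseModalities(b, c(1, 0, 0))
  expect_equal(X, c(b@x1, numeric(6), numeric(4)))
  ones <- new("ModalityBundle", id = "o", x1 = rep(1, 2), x2 = rep(1, 2),
              x3 = rep(1, 2))
  expect_equal(fuseModalities(ones, rep(1 / 3, 3)), rep(1 / 3, 6))
  w <- c(0.2, 0.5, 0.3)
  X2 <- fuseModalities(b, w)
  bound <- max(w) * (sqrt(sum(b@x1^2)) + sqrt(sum(b@x2^2)) +
                       sqrt(sum(b@x3^2)))
  expect_lte(sqrt(sum(X2^2)), bound + 1e-12)
})

test_that("residual refinement is identity at zero weights and matches
           the sliding-window oracle otherwise", {
  m <- smallScrn(); b <- smallBundle()
  fw <- scrnForward(b, m)
  m0 <- m
  m0$conv <- list(w1 = numeric(3), cb1 = 0, w2 = numeric(3), cb2 = 0)
  expect_identical(residualRefine(fw$X, m0), fw$X)
  expect_length(fw$y, 18)
  # sliding-window two-layer conv oracle for y - X
  m$conv$w2 <- c(0.3, -0.2, 0.5)   # non-degenerate second kernel
  fw <- scrnForward(b, m)
  slide <- function(x, w, bias) {
    n <- length(x)
    sapply(seq_len(n), function(i) {
      s <- bias
      for (j in 1:3) {
        k <- i + j - 2
        if (k >= 1 && k <= n) s <- s + w[j] * x[k]
      }
      s
    })
  }
  lr <- function(x) pmax(x, 0.01 * x)
  h1 <- lr(slide(fw$X, m$conv$w1, m$conv$cb1))
  h2 <- lr(slide(h1, m$conv$w2, m$conv$cb2))
  expect_lt(max(abs((fw$y - fw$X) - h2)), 1e-6)
})

test_that("end-to-end fusion is deterministic and differentiable", {
  m <- smallScrn(); b <- smallBundle()
  m$conv$w2 <- c(0.1, 0.2, -0.3)
  f1 <- scrnForward(b, m, keep = TRUE)
  expect_identical(f1$y, scrnForward(b, m)$y)
  # numeric spot-check of the analytic parameter gradients
  lossAt <- function(mm) sum(scrnForward(b, mm)$y^2)
  g <- molviews:::scrnBackwardInternal(2 * f1$y, m, f1$cache)
  eps <- 1e-7
  m2 <- m; m2$proj$W2[3, 4] <- m2$proj$W2[3, 4] + eps
  expect_equal(g$proj$W2[3, 4], (lossAt(m2) - lossAt(m)) / eps,
               tolerance = 1e-3)
  m3 <- m; m3$gate$u3[2] <- m3$gate$u3[2] + eps
  expect_equal(g$gate$u3[2], (lossAt(m3) - lossAt(m)) / eps,
               tolerance = 1e-3)
})
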