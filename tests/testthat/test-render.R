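# Canonical orientation, six-view rasterization, .npy archive

test_that("canonical orientation centers, aligns and is rotation-invariant", {
  benzene <- canonicalOrient(
    embedConformer(parseSmiles("c1ccccc1", "benzene"), 1))
  co <- atomCoords(benzene)
  expect_lt(max(abs(colMeans(co))), 1e-8)
  # applying the map twice is (numerically) a fixed point
  again <- canonicalOrient(benzene)
  expect_lt(max(abs(atomCoords(again) - co)), 1e-6)
  # a randomly rotated copy canonicalizes to the same coordinates
  for (s in 1:3) {
    rot <- randomRotation(s)
    rotated <- benzene
    rotated@coords <- co %*% t(rot)
    expect_lt(max(abs(atomCoords(canonicalOrient(rotated)) - co)), 1e-5)
  }
})

test_that("single atoms orient to the origin and render identical views", {
  single <- parseSmiles("C", "methane")
  single@coords <- matrix(c(3, 2, 1), 1)
  single@elements <- "C"
  single@bonds <- matrix(integer(0), 0, 3)
  oriented <- canonicalOrient(single)
  expect_equal(atomCoords(oriented), matrix(0, 1, 3))
  t1 <- renderViews(oriented, 64, 64)
  d <- viewData(t1)
  for (v in 2:6) expect_identical(d[, 1, , ], d[, v, , ])
  expect_equal(d[4, 1, 32, 32], 1)   # disc covers the center
  expect_equal(d[4, 1, 1, 1], 0)     # corners are background
})

test_that("rendering is deterministic with opposite-view mirror symmetry", {
  fz <- featurized20()
  t1 <- renderViews(fz$mols[[1]], 64, 64)
  expect_identical(viewData(t1), viewData(renderViews(fz$mols[[1]], 64, 64)))
  # front/back, right/left, top/bottom are horizontal mirrors
  pairs <- list(c(1, 3), c(2, 6), c(5, 4))
  mad <- sapply(fz$tensors, function(tt) {
    d <- viewData(tt)
    W <- dim(d)[4]
    mean(sapply(pairs, function(p)
      mean(abs(d[, p[1], , ] - d[, p[2], , W:1]))))
  })
  expect_lt(max(mad), 0.02)
})

test_that("enantiomers render distinct tensors", {
  r <- renderViews(canonicalOrient(
    embedConformer(parseSmiles("[C@H](F)(Cl)Br", "R"), 1)))
  s <- renderViews(canonicalOrient(
    embedConformer(parseSmiles("[C@@H](F)(Cl)Br", "S"), 1)))
  expect_gt(sqrt(sum((viewData(r) - viewData(s))^2)), 0)
})

test_that("alpha channel marks geometry and values stay in [0, 1]", {
  fz <- featurized20()
  for (tt in fz$tensors[1:5]) {
    d <- viewData(tt)
    expect_true(all(d >= 0 & d <= 1))
    expect_gt(mean(d[4, , , ] > 0), 0)            # some occupancy
    bg <- d[4, , , ] == 0
    for (ch in 1:3)
      expect_true(all(d[ch, , , ][bg] == 0))      # background is clean
  }
})

test_that(".npy archive round-trips bitwise and rejects bad files", {
  t0 <- new("ViewTensor", data = array(runif(4 * 6 * 64 * 64),
                                       c(4, 6, 64, 64)))
  path <- withr::local_tempfile(fileext = ".npy")
  saveViewTensor(t0, path)
  expect_identical(viewData(loadViewTensor(path)), viewData(t0))
  # wrong shape
  molviews:::writeNpy(array(runif(3 * 6 * 8 * 8), c(3, 6, 8, 8)), path)
  expect_error(loadViewTensor(path), class = "FormatError")
  # truncated payload
  saveViewTensor(t0, path)
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[seq_len(length(full) - 4096)], path)
  expect_error(loadViewTensor(path), class = "FormatError")
  # not npy at all
  writeLines("hello", path)
  expect_error(loadViewTensor(path), class = "FormatError")
})
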