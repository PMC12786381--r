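# SMILES parsing, conformers, fingerprints, graph embeddings

test_that("parsing canonicalizes and exposes the heavy-atom graph", {
  m <- parseSmiles("CCO", "ethanol")
  expect_s4_class(m, "MoleculeRecord")
  expect_length(atomElements(m), 3)
  expect_equal(nrow(bondTable(m)), 2)
  expect_true(all(bondTable(m)[, "order"] == 1))
  # spelling-invariant canonical form
  expect_identical(canonicalSmiles(parseSmiles("OCC")),
                   canonicalSmiles(m))
  # formal charge from bracket atoms
  expect_equal(parseSmiles("CC(=O)[O-]")@charge, -1L)
  expect_equal(parseSmiles("C[N+](C)(C)C")@charge, 1L)
})

test_that("malformed SMILES raise ParseError", {
  expect_error(parseSmiles("C("), class = "ParseError")
  expect_error(parseSmiles("C1CC"), class = "ParseError")
  expect_error(parseSmiles(""), class = "ParseError")
  expect_error(parseSmiles("Cx"), class = "ParseError")
})

test_that("conformer embedding is deterministic and geometrically sane", {
  methane <- embedConformer(parseSmiles("C", "methane"), seed = 7)
  expect_length(atomElements(methane), 5)
  co <- atomCoords(methane)
  hCentroid <- colMeans(co[atomElements(methane) == "H", , drop = FALSE])
  cIdx <- which(atomElements(methane) == "C")
  expect_lt(sqrt(sum((co[cIdx, ] - hCentroid)^2)), 0.01)
  expect_true(is.finite(conformerEnergy(methane)))

  again <- embedConformer(parseSmiles("C", "methane"), seed = 7)
  expect_identical(atomCoords(again), co)

  benzene <- embedConformer(parseSmiles("c1ccccc1", "benzene"), seed = 1)
  ring <- atomCoords(benzene)[atomElements(benzene) == "C", ]
  centered <- sweep(ring, 2, colMeans(ring))
  normal <- svd(centered)$v[, 3]
  expect_lt(max(abs(centered %*% normal)), 0.1)
})

test_that("fingerprints are deterministic, spelling-invariant and typed", {
  m1 <- parseSmiles("CCO"); m2 <- parseSmiles("OCC")
  for (kind in c("morgan", "maccs", "topological_torsion")) {
    f1 <- computeFingerprint(m1, kind)
    expect_true(all(f1 %in% c(0L, 1L)))
    expect_identical(f1, computeFingerprint(m1, kind))  # repeat call
    expect_identical(f1, computeFingerprint(m2, kind))  # spelling
  }
  morgan <- computeFingerprint(m1, "morgan", 1024)
  expect_length(morgan, 1024)
  expect_gte(sum(morgan), 1)
  # MACCS has a fixed catalog size regardless of the n_bits argument
  expect_length(computeFingerprint(m1, "maccs", 4096), 166)
  expect_error(computeFingerprint(m1, "daylight"), class = "ConfigError")
})

test_that("graph embedding has the contracted shape and invariances", {
  params <- defaultGraphEncoderParams(d2 = 64, seed = 1)
  m <- parseSmiles("CC(C)c1ccccc1O", "carvacrol-ish")
  v <- computeGraphEmbedding(m, params)
  expect_length(v, 64)
  expect_true(all(is.finite(v)))
  expect_identical(v, computeGraphEmbedding(m, params))  # determinism
  # atom-order permutation via a different SMILES spelling of the
  # same molecule canonicalizes to the same embedding
  perm <- parseSmiles("Oc1ccccc1C(C)C", "permuted")
  expect_lt(max(abs(v - computeGraphEmbedding(perm, params))), 1e-6)
  # single-atom molecule: empty bond channel is valid
  single <- computeGraphEmbedding(parseSmiles("C"), params)
  expect_length(single, 64)
  expect_true(all(is.finite(single)))
})

test_that("SDF round trip preserves conformers", {
  mols <- list(embedConformer(parseSmiles("C", "m1"), 1),
               embedConformer(parseSmiles("c1ccccc1", "m2"), 1))
  path <- withr::local_tempfile(fileext = ".sdf")
  writeMoleculeSdf(mols, path)
  back <- readMoleculeSdf(path)
  expect_length(back, 2)
  expect_equal(atomCoords(back[[2]]), atomCoords(mols[[2]]),
               tolerance = 1e-4)
  expect_identical(canonicalSmiles(back[[2]]), canonicalSmiles(mols[[2]]))
})
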