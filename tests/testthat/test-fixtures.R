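# Synthetic fixture generators: determinism, validity, planted signal

test_that("molecule sets are valid, deterministic and carry enantiomers", {
  sm <- genMoleculeSet(20, seed = 0, include_enantiomer_pairs = TRUE)
  expect_equal(nrow(sm), 20)
  expect_identical(sm, genMoleculeSet(20, seed = 0,
                                      include_enantiomer_pairs = TRUE))
  # all parse (conformer success is exercised by the featurized cache)
  mols <- lapply(seq_len(nrow(sm)), function(i)
    parseSmiles(sm$smiles[i], sm$id[i]))
  expect_length(mols, 20)
  # the flagged pair differs only by stereo descriptors
  strip <- function(s) gsub("[@]", "", s)
  expect_false(identical(canonicalSmiles(mols[[1]]),
                         canonicalSmiles(mols[[2]])))
  expect_identical(strip(canonicalSmiles(mols[[1]])),
                   strip(canonicalSmiles(mols[[2]])))
})

test_that("planted graphs are reproducible with a stored Bayes bound", {
  spec <- plantedGraphSpec(n_drugs = 50L, n_partners = 40L,
                           latent_dim = 8L, noise_sd = 0,
                           edge_logit_scale = 3, seed = 11L)
  m1 <- genInteractionGraph(spec)
  m2 <- genInteractionGraph(spec)
  expect_identical(m1$edges, m2$edges)
  expect_identical(m1$bayes_auc, m2$bayes_auc)
  expect_gte(m1$bayes_auc, 0.95)
  expect_equal(dim(m1$drug_signal), c(50, 64))
  expect_equal(dim(m1$partner_features), c(40, 64))
  # scale 0: no planted signal, density near 1/2
  expect_warning(flat <- genInteractionGraph(
    plantedGraphSpec(edge_logit_scale = 0, seed = 2)),
    "signal absent")
  dens <- mean(flat$edges$label)
  expect_lt(abs(dens - 0.5), 3 * sqrt(0.25 / nrow(flat$edges)) + 0.01)
})

test_that("toxicity endpoints are an exact descriptor function at zero
           noise", {
  sm <- genMoleculeSet(10, seed = 4)
  mols <- lapply(seq_len(nrow(sm)), function(i)
    parseSmiles(sm$smiles[i], sm$id[i]))
  e0 <- genToxicityEndpoints(mols, seed = 1, noise_sd = 0)
  e0b <- genToxicityEndpoints(mols, seed = 99, noise_sd = 0)
  expect_equal(e0$value, e0b$value)      # noiseless: seed-independent
  en <- genToxicityEndpoints(mols, seed = 1, noise_sd = 0.5)
  expect_identical(en, genToxicityEndpoints(mols, seed = 1,
                                            noise_sd = 0.5))
  expect_false(isTRUE(all.equal(e0$value, en$value)))
  coefs <- attr(e0, "coefficients")
  expect_length(coefs, 4)
  # spot-check one molecule against the documented linear form
  g <- molviews:::heavyGraph(mols[[1]])
  na <- length(g$elements)
  rings <- nrow(g$bonds) - na + 1      # connected molecule
  hf <- mean(g$elements != "C")
  expect_equal(e0$value[1],
               unname(coefs[1] + coefs[2] * na + coefs[3] * rings +
                        coefs[4] * hf))
})

test_that("manifests round-trip through the plain-text layout", {
  man <- genInteractionGraph(plantedGraphSpec(n_drugs = 6L,
                                              n_partners = 5L, seed = 3L))
  dir <- withr::local_tempdir()
  writeFixtureManifest(man, dir,
                       smiles = genMoleculeSet(6, seed = 3))
  expect_true(all(file.exists(file.path(
    dir, c("smiles.tsv", "edges.tsv", "partner_features.tsv",
           "drug_signal.tsv", "manifest.json")))))
  back <- readFixtureManifest(dir)
  expect_equal(back$edges$label, man$edges$label)
  expect_equal(back$bayes_auc, man$bayes_auc, tolerance = 1e-12)
  expect_equal(unname(back$partner_features),
               unname(man$partner_features), tolerance = 1e-12)
  expect_identical(back$spec_hash, man$spec_hash)
})
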