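# Shared fixtures, generated in code and memoized for the whole run:
# conformer generation and autoencoder training are the expensive steps,
# so every test file pulls from this cache instead of regenerating.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

# 20 grammar molecules (incl. one enantiomer pair), conformers, tensors,
# bundles - the renderer/autoencoder fixture set
featurized20 <- function() cachedFixture("f20", {
  sm <- genMoleculeSet(20, seed = 0, include_enantiomer_pairs = TRUE)
  featurizeMolecules(sm, initSpatialAutoencoder(spatialConfig(), 0),
                     seed = 0)
})

# autoencoder trained on the 20 fixtures (the training-contract run)
trainedAutoencoder50 <- function() cachedFixture("ae50", {
  trainAutoencoder(featurized20()$tensors, spatialConfig(),
                   epochs = 50, seed = 0)
})

# planted bipartite interaction problem, full drug featurization path
plantedPipeline <- function() cachedFixture("planted", {
  man <- genInteractionGraph(plantedGraphSpec(
    n_drugs = 50L, n_partners = 40L, latent_dim = 8L, noise_sd = 0,
    edge_logit_scale = 3, seed = 7L))
  sm <- genMoleculeSet(50, seed = 7)
  sm$id <- man$drug_ids
  fz <- featurizeMolecules(sm, initSpatialAutoencoder(spatialConfig(), 7),
                           injection = man$drug_signal, seed = 7)
  scrn <- initScrn(scrnConfig(d3 = length(fz$bundles[[1]]@x3)), 7)
  E <- drugEmbeddingMatrix(fz$bundles, scrn)
  graph <- buildInteractionGraph(E, man$partner_features,
                                 man$edges[man$edges$label == 1, ], "dti")
  list(man = man, smiles = sm, fz = fz, scrn = scrn, E = E, graph = graph)
})

# one held-out evaluation of the planted problem for a given split seed
plantedHeldOutAuc <- function(seed, cfg = gcnConfig()) {
  pp <- plantedPipeline()
  sp <- edgeSplit(pp$graph, 0.2, seed = seed)
  testPos <- sp$test[sp$test$label == 1, c("i", "j")]
  fit <- trainLinkPredictor(sp$train, cfg, seed = seed,
                            exclude_pairs = as.matrix(testPos))
  S <- linkScores(fit, sp$train)
  classificationMetrics(S[cbind(sp$test$i, sp$test$j)], sp$test$label)
}

randomRotation <- function(seed) {
  set.seed(seed)
  th <- runif(3) * 2 * pi
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]),
                 0, 0, 0, 1), 3)
  Rx %*% Ry %*% Rz
}

randomSymmetricGraph <- function(nn, nEdges, seed) {
  set.seed(seed)
  A <- matrix(0, nn, nn)
  ut <- which(upper.tri(A))
  on <- sample(ut, min(nEdges, length(ut)))
  A[on] <- 1
  A + t(A)
}
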