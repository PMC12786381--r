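# Classification/regression metrics, scaffolds, interpretability ops

test_that("ROC-AUC equals the concordant-pair oracle, with tie credit", {
  # tie rule: labels (1,0) with equal scores give exactly 0.5
  expect_equal(classificationMetrics(c(0.5, 0.5), c(1, 0))$roc_auc, 0.5)
  pairAuc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(9)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    s <- round(runif(n), sample(1:3, 1))   # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(classificationMetrics(s, y)$roc_auc, pairAuc(s, y),
                 tolerance = 1e-9)
  }
  # independent cross-check against pROC on one drawn instance
  s3 <- runif(120); y3 <- rbinom(120, 1, 0.5)
  expect_equal(classificationMetrics(s3, y3)$roc_auc,
               as.numeric(suppressMessages(pROC::auc(y3, s3))),
               tolerance = 1e-9)
})

test_that("perfect separation yields AUC, KS and F1 of one", {
  s <- c(0.9, 0.8, 0.2, 0.1); y <- c(1, 1, 0, 0)
  m <- classificationMetrics(s, y)
  expect_equal(m$roc_auc, 1); expect_equal(m$ks, 1)
  expect_equal(m$aupr, 1); expect_equal(m$f1, 1)
  expect_equal(m$accuracy, 1)
  # KS bounded in [0, 1] and equals the max ECDF gap
  set.seed(2)
  s2 <- runif(200); y2 <- rbinom(200, 1, 0.5)
  ks <- classificationMetrics(s2, y2)$ks
  expect_gte(ks, 0); expect_lte(ks, 1)
  suppressWarnings(ks2 <- stats::ks.test(s2[y2 == 1], s2[y2 == 0])$statistic)
  expect_equal(ks, unname(ks2), tolerance = 1e-9)
  # single class: NA rank metrics with a warning, threshold metrics live
  expect_warning(m1 <- classificationMetrics(c(0.2, 0.8), c(1, 1)),
                 class = "UndefinedMetricError")
  expect_true(is.na(m1$roc_auc))
  expect_equal(m1$recall, 0.5)
})

test_that("regression metrics match hand arithmetic and identities", {
  m <- regressionMetrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$mse, 4 / 3); expect_equal(m$mae, 2 / 3)
  expect_equal(m$medae, 0); expect_equal(m$rmse, sqrt(4 / 3))
  p <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$rmse, 0); expect_equal(p$r2, 1); expect_equal(p$evs, 1)
  # constant mean prediction: r2 exactly 0
  y <- c(2, 4, 6, 8)
  expect_equal(regressionMetrics(y, rep(mean(y), 4))$r2, 0)
  expect_warning(z <- regressionMetrics(c(0, 1), c(1, 1)),
                 class = "UndefinedMetricError")
  expect_true(is.na(z$mape))
})

test_that("Murcko scaffolds strip side chains and group frameworks", {
  expect_identical(murckoScaffold("Cc1ccccc1"), murckoScaffold("c1ccccc1"))
  expect_identical(murckoScaffold("CCCCCC"), "")       # acyclic
  expect_identical(murckoScaffold("CC(C)CCO"), "")
  # ring + linker + ring survives with the linker
  bp <- murckoScaffold("c1ccccc1Cc1ccccc1")
  expect_true(nzchar(bp))
  expect_identical(murckoScaffold("Cc1ccc(Cc2ccccc2)cc1"), bp)
})

test_that("scaffold split never leaks a scaffold and honors test_frac", {
  sm <- genMoleculeSet(24, seed = 5)
  mols <- lapply(seq_len(nrow(sm)), function(i)
    parseSmiles(sm$smiles[i], sm$id[i]))
  scaffolds <- vapply(mols, murckoScaffold, character(1))
  for (s in 1:100) {
    sp <- scaffoldSplit(mols, 0.25, seed = s)
    trSc <- unique(scaffolds[match(sp$train_ids, sm$id)])
    teSc <- unique(scaffolds[match(sp$test_ids, sm$id)])
    expect_length(intersect(trSc, teSc), 0)
    expect_gte(length(sp$test_ids), 0.25 * nrow(sm))
  }
  # 4 distinct scaffolds at test_frac 0.25: exactly one group held out
  four <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1")
  sp4 <- scaffoldSplit(four, 0.25, seed = 1)
  teSc <- unique(vapply(sp4$test_ids, function(id)
    sp4$scaffold_map[[id]], character(1)))
  expect_length(teSc, 1)
  expect_warning(scaffoldSplit(c("c1ccccc1", "Cc1ccccc1"), 0.5, 1),
                 "split impossible")
})

test_that("scaffold diversity: uniform entropy is ln n, ratio bounds hold", {
  u <- scaffoldDiversity(letters[1:7], scaffolds = TRUE)
  expect_equal(u$diversity_ratio, 1)
  expect_equal(u$shannon_entropy, log(7), tolerance = 1e-12)
  one <- scaffoldDiversity(rep("s", 5), scaffolds = TRUE)
  expect_equal(one$diversity_ratio, 1 / 5)
  expect_equal(one$shannon_entropy, 0)
  counts211 <- scaffoldDiversity(c("a", "a", "b", "c"), scaffolds = TRUE)
  expect_equal(counts211$shannon_entropy,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-9)
})

test_that("orphan protocol isolates the entity and builds a 1:1 eval set", {
  pp <- plantedPipeline()
  drug <- drugIds(pp$graph)[3]
  res <- orphanEntityProtocol(pp$graph, drug, seed = 1,
                              cfg = gcnConfig(epochs = 60L))
  n <- length(drugIds(pp$graph))
  node <- match(drug, drugIds(pp$graph))
  expect_equal(sum(adjacency(res$train_graph)[node, ]), 0)
  expect_equal(sum(adjacency(res$train_graph)[, node]), 0)
  expect_equal(sum(res$eval_set$label == 1), sum(res$eval_set$label == 0))
  expect_equal(res$ranked$rank, seq_len(nrow(res$ranked)))
  expect_true(all(diff(res$ranked$score) <= 0))
  expect_error(orphanEntityProtocol(pp$graph, "nope", 1),
               class = "KeyError")
})

test_that("modality weight report rows are probability vectors", {
  pp <- plantedPipeline()
  rep_ <- modalityWeightReport(pp$scrn, pp$fz$bundles[1:10])
  expect_equal(dim(rep_$per_molecule), c(10, 3))
  expect_true(all(abs(rowSums(rep_$per_molecule) - 1) < 1e-9))
  expect_equal(sum(rep_$mean), 1, tolerance = 1e-9)
  # symmetric (zero-logit) init: means exactly 1/3 each
  expect_true(all(abs(rep_$mean - 1 / 3) < 0.05))
  expect_true(all(abs(rep_$per_molecule - 1 / 3) < 1e-12))
  rep2 <- modalityWeightReport(pp$scrn, pp$fz$bundles[1:10])
  expect_identical(rep_$per_molecule, rep2$per_molecule)
})

test_that("gradCam contracts: zero input, bounds, layer validation", {
  model <- initSpatialAutoencoder(spatialConfig(), 1)
  head <- gradcamLinearHead(rep(1, 128))
  zero <- gradCam(model, array(0, c(4, 6, 64, 64)), head, 2)
  expect_true(all(zero == 0))
  fz <- featurized20()
  cams <- gradCam(model, fz$tensors[[1]], head, 2)
  expect_equal(dim(cams), c(6, 64, 64))
  expect_true(all(cams >= 0 & cams <= 1))
  expect_error(gradCam(model, fz$tensors[[1]], head, 9),
               class = "ConfigError")
})
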