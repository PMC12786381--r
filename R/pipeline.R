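## End-to-end orchestration: featurization, training, explanation.
## File-based commands (cmdFeaturize / cmdTrain / cmdExplain) wrap the
## in-memory pipeline used programmatically and by the CLI script in
## inst/cli/molviews.R.

#' Assemble a run configuration
#'
#' A single serializable list driving the pipeline commands; its hash is
#' stamped into every artifact so a run is reproducible from its
#' manifest.
#'
#' @param task "dti", "ddi", "dmi" or "tox".
#' @param smiles path to a TSV (id <tab> smiles).
#' @param edges path to an edge TSV (drug_id, partner_id, label).
#' @param partner_features path to a partner feature TSV (id + columns).
#' @param endpoints path to an endpoint TSV (id, value) for "tox".
#' @param out output directory.
#' @param seed master seed.
#' @param H,W render resolution.
#' @param fingerprint_kind,n_bits 1D fingerprint settings.
#' @param pretrain_epochs autoencoder pretraining epochs (0 = skip).
#' @param gcn a \code{\link{gcnConfig}}.
#' @param train_scrn train fusion jointly with the GCN.
#' @param test_frac held-out fraction of positive pairs.
#' @return config list with a config_hash element.
#' @export
runConfig <- function(task = c("dti", "ddi", "dmi", "tox"),
                      smiles = NULL, edges = NULL,
                      partner_features = NULL, endpoints = NULL,
                      out = "molviews_run", seed = 0L,
                      H = 64L, W = 64L,
                      fingerprint_kind = "morgan", n_bits = 1024L,
                      pretrain_epochs = 30L,
                      gcn = gcnConfig(), train_scrn = FALSE,
                      test_frac = 0.2) {
  cfg <- list(task = match.arg(task), smiles = smiles, edges = edges,
              partner_features = partner_features, endpoints = endpoints,
              out = out, seed = as.integer(seed), H = as.integer(H),
              W = as.integer(W), fingerprint_kind = fingerprint_kind,
              n_bits = as.integer(n_bits),
              pretrain_epochs = as.integer(pretrain_epochs),
              gcn = gcn, train_scrn = isTRUE(train_scrn),
              test_frac = test_frac)
  cfg$config_hash <- configHash(cfg)
  cfg
}

#' Featurize molecules into modality bundles
#'
#' For each molecule: parse + canonicalize, embed an MMFF94s conformer,
#' canonically orient, render the six views, and compute the three
#' modalities (fingerprint x1, graph embedding x2, directional spatial
#' feature x3 from the provided or freshly initialized spatial model).
#' An optional injection matrix (id-matched rows) is added onto x2 —
#' used by the planted-graph fixtures to make link labels recoverable
#' from molecule identity.
#'
#' @param smilesDf data.frame(id, smiles).
#' @param spatial spatial autoencoder parameters (default: seeded init).
#' @param fingerprint_kind,n_bits fingerprint settings.
#' @param graph_params graph-encoder parameters.
#' @param injection optional matrix with rownames = molecule ids whose
#'   rows are added to x2.
#' @param seed conformer/model seed.
#' @param on_error "stop" or "skip" (skipped molecules are dropped with
#'   a message).
#' @return list(mols, tensors, bundles), each keyed by id.
#' @export
featurizeMolecules <- function(smilesDf, spatial = NULL,
                               fingerprint_kind = "morgan",
                               n_bits = 1024L,
                               graph_params = defaultGraphEncoderParams(),
                               injection = NULL, seed = 0L,
                               on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (is.null(spatial))
    spatial <- initSpatialAutoencoder(spatialConfig(), seed)
  failed <- character(0)
  parsed <- list()
  for (r in seq_len(nrow(smilesDf))) {
    id <- as.character(smilesDf$id[r])
    res <- tryCatch(parseSmiles(smilesDf$smiles[r], id),
                    molviewsError = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      message(sprintf("skipping '%s': %s", id, conditionMessage(res)))
      failed <- c(failed, id)
    } else parsed[[id]] <- res
  }
  embedded <- embedConformerBatch(parsed, seed)
  emFail <- attr(embedded, "failed")
  for (r in seq_len(nrow(emFail))) {
    msg <- sprintf("skipping '%s': %s", emFail$id[r], emFail$reason[r])
    if (on_error == "stop") stopMv("ConformerError", "%s", msg)
    message(msg)
  }
  failed <- c(failed, emFail$id)
  mols <- list(); tensors <- list(); bundles <- list()
  for (id in names(embedded)) {
    mol <- canonicalOrient(embedded[[id]])
    tens <- renderViews(mol, spatial$cfg$H, spatial$cfg$W)
    x1 <- as.numeric(computeFingerprint(mol, fingerprint_kind, n_bits))
    x2 <- as.numeric(computeGraphEmbedding(mol, graph_params))
    if (!is.null(injection) && id %in% rownames(injection))
      x2 <- x2 + as.numeric(injection[id, ])
    x3 <- as.numeric(directionalEncode(groupViews(tens), spatial))
    mols[[id]] <- mol
    tensors[[id]] <- tens
    bundles[[id]] <- new("ModalityBundle", id = id, x1 = x1, x2 = x2,
                         x3 = x3)
  }
  if (length(failed) > 0.1 * nrow(smilesDf))
    stopMv("InputError", "more than 10%% of molecules failed (%d of %d)",
           length(failed), nrow(smilesDf))
  list(mols = mols, tensors = tensors, bundles = bundles, failed = failed)
}

#' Fused drug embedding matrix
#'
#' Runs the SCRN over a list of bundles and stacks the refined
#' embeddings y as rows.
#'
#' @param bundles list of \linkS4class{ModalityBundle}s.
#' @param scrn SCRN parameters (see \code{\link{initScrn}}).
#' @return matrix (n x (d1+d2+d3)) with molecule ids as rownames.
#' @export
drugEmbeddingMatrix <- function(bundles, scrn) {
  E <- t(vapply(bundles, function(b) scrnForward(b, scrn)$y,
                numeric(scrn$cfg$d1 + scrn$cfg$d2 + scrn$cfg$d3)))
  rownames(E) <- vapply(bundles, molId, character(1))
  E
}

#' Featurize a SMILES file to disk (resumable)
#'
#' Writes one .npy view tensor per molecule plus fingerprint and
#' graph-embedding tables; molecules whose tensor file already exists
#' are skipped, so reruns are idempotent. Per-molecule failures are
#' logged and skipped; the run fails only if more than 10 percent fail.
#'
#' @param config a \code{\link{runConfig}} with \code{smiles} set.
#' @return invisibly, the output directory.
#' @export
cmdFeaturize <- function(config) {
  stopifnot(!is.null(config$smiles))
  df <- readSmilesFile(config$smiles)
  dir.create(file.path(config$out, "tensors"), recursive = TRUE,
             showWarnings = FALSE)
  spatial <- initSpatialAutoencoder(
    spatialConfig(H = config$H, W = config$W), config$seed)
  failPath <- file.path(config$out, "failed_ids.txt")
  knownFailed <- if (file.exists(failPath)) readLines(failPath)
                 else character(0)
  done <- vapply(df$id, function(id)
    file.exists(file.path(config$out, "tensors", paste0(id, ".npy"))),
    logical(1))
  todo <- df[!done & !df$id %in% knownFailed, , drop = FALSE]
  if (nrow(todo) > 0) {
    fz <- featurizeMolecules(todo, spatial,
                             fingerprint_kind = config$fingerprint_kind,
                             n_bits = config$n_bits, seed = config$seed,
                             on_error = "skip")
    for (id in names(fz$tensors))
      saveViewTensor(fz$tensors[[id]],
                     file.path(config$out, "tensors", paste0(id, ".npy")))
    appendFeatureTable(config$out, fz$bundles)
    if (length(fz$failed))
      writeLines(union(knownFailed, fz$failed), failPath)
  }
  writeRunStamp(config)
  invisible(config$out)
}

appendFeatureTable <- function(out, bundles) {
  path <- file.path(out, "features.tsv")
  rows <- lapply(bundles, function(b)
    data.frame(id = b@id,
               x1 = paste(b@x1, collapse = ","),
               x2 = paste(signif(b@x2, 8), collapse = ","),
               x3 = paste(signif(b@x3, 8), collapse = ",")))
  df <- do.call(rbind, rows)
  if (file.exists(path)) {
    old <- read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character")
    df <- rbind(old[!old$id %in% df$id, ], df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readFeatureTable <- function(out) {
  df <- read.table(file.path(out, "features.tsv"), sep = "\t",
                   header = TRUE, colClasses = "character")
  bundles <- lapply(seq_len(nrow(df)), function(r)
    new("ModalityBundle", id = df$id[r],
        x1 = as.numeric(strsplit(df$x1[r], ",")[[1]]),
        x2 = as.numeric(strsplit(df$x2[r], ",")[[1]]),
        x3 = as.numeric(strsplit(df$x3[r], ",")[[1]])))
  names(bundles) <- df$id
  bundles
}

writeRunStamp <- function(config) {
  jsonlite::write_json(list(config_hash = config$config_hash,
                            seed = config$seed,
                            timestamp = format(Sys.time(), "%Y-%m-%d")),
                       file.path(config$out, "run.json"),
                       auto_unbox = TRUE)
}

#' Train a link predictor (or property head) from files
#'
#' Loads featurized molecules (running \code{\link{cmdFeaturize}} if
#' needed), optionally pretrains the spatial autoencoder on the
#' rendered tensors, fuses modalities with the SCRN, builds the
#' interaction graph from the edge list, splits edges, trains, and
#' writes a metrics JSON (classification report for link tasks,
#' regression report for "tox") plus an RDS checkpoint stamped with
#' the config hash.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list(fit, metrics, paths) invisibly.
#' @export
cmdTrain <- function(config) {
  if (!file.exists(file.path(config$out, "features.tsv")))
    cmdFeaturize(config)
  bundles <- readFeatureTable(config$out)
  scfg <- spatialConfig(H = config$H, W = config$W)
  spatial <- initSpatialAutoencoder(scfg, config$seed)
  if (config$pretrain_epochs > 0) {
    tens <- lapply(names(bundles), function(id)
      loadViewTensor(file.path(config$out, "tensors",
                               paste0(id, ".npy"))))
    tr <- trainAutoencoder(tens, scfg, epochs = config$pretrain_epochs,
                           seed = config$seed)
    spatial <- tr$model
    ## refresh x3 with the pretrained directional paths
    for (k in seq_along(bundles)) {
      id <- names(bundles)[k]
      bundles[[id]]@x3 <- as.numeric(
        directionalEncode(groupViews(tens[[k]]), spatial))
    }
    utils::write.csv(data.frame(epoch = seq_along(tr$loss) - 1,
                                loss = tr$loss),
                     file.path(config$out, "autoencoder_loss.csv"),
                     row.names = FALSE)
  }
  d3 <- length(bundles[[1]]@x3)
  scrn <- initScrn(scrnConfig(d1 = config$n_bits,
                              d2 = length(bundles[[1]]@x2), d3 = d3),
                   config$seed)
  if (config$task == "tox") {
    stopifnot(!is.null(config$endpoints))
    ep <- read.table(config$endpoints, sep = "\t", header = TRUE)
    E <- drugEmbeddingMatrix(bundles[ep$id], scrn)
    fitH <- trainPropertyHead(E, ep$value, seed = config$seed)
    pred <- predictProperty(E, fitH$head)
    metrics <- regressionMetrics(ep$value, pred)
    fit <- fitH
  } else {
    stopifnot(!is.null(config$edges))
    edges <- read.table(config$edges, sep = "\t", header = TRUE,
                        colClasses = c("character", "character",
                                       "integer"))
    names(edges)[1:3] <- c("drug", "partner", "label")
    pf <- read.table(config$partner_features, sep = "\t", header = TRUE)
    pfm <- as.matrix(pf[, -1]); rownames(pfm) <- pf[[1]]
    E <- drugEmbeddingMatrix(bundles, scrn)
    graph <- buildInteractionGraph(E, pfm, edges[edges$label == 1, ],
                                   config$task)
    sp <- edgeSplit(graph, config$test_frac, config$seed)
    fit <- trainLinkPredictor(
      sp$train, config$gcn, seed = config$seed,
      scrn = if (config$train_scrn)
        list(model = scrn, bundles = bundles) else NULL)
    if (config$train_scrn) scrn <- fit$scrn
    S <- linkScores(fit, sp$train)
    metrics <- classificationMetrics(S[cbind(sp$test$i, sp$test$j)],
                                     sp$test$label)
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  metricsPath <- file.path(config$out, "metrics.json")
  jsonlite::write_json(c(metrics, list(config_hash = config$config_hash,
                                       seed = config$seed)),
                       metricsPath, auto_unbox = TRUE, digits = NA)
  ckpt <- file.path(config$out, "checkpoint.rds")
  saveRDS(list(spatial = spatial, scrn = scrn, fit = fit,
               config = config), ckpt)
  writeRunStamp(config)
  invisible(list(fit = fit, metrics = metrics,
                 paths = c(metrics = metricsPath, checkpoint = ckpt)))
}

#' Explain one molecule from a trained checkpoint
#'
#' Writes six Grad-CAM heatmap PNGs (saliency-tinted views) and a
#' gate-weight CSV row for the molecule.
#'
#' @param config a \code{\link{runConfig}} whose out dir holds a
#'   checkpoint from \code{\link{cmdTrain}}.
#' @param molecule_id id present in the featurized set.
#' @return invisibly, the written file paths.
#' @export
cmdExplain <- function(config, molecule_id) {
  ckpt <- file.path(config$out, "checkpoint.rds")
  stopifnot(file.exists(ckpt))
  st <- readRDS(ckpt)
  tensPath <- file.path(config$out, "tensors",
                        paste0(molecule_id, ".npy"))
  if (!file.exists(tensPath))
    stopMv("KeyError", "unknown molecule id '%s'", molecule_id)
  tens <- loadViewTensor(tensPath)
  bundles <- readFeatureTable(config$out)
  if (!molecule_id %in% names(bundles))
    stopMv("KeyError", "unknown molecule id '%s'", molecule_id)
  head <- withSeed(config$seed,
                   gradcamLinearHead(rnorm(st$spatial$cfg$latent_dim)))
  cams <- gradCam(st$spatial, tens, head)
  x <- viewData(tens)
  paths <- character(0)
  for (vw in seq_len(6)) {
    img <- aperm(x[1:3, vw, , ], c(2, 3, 1))
    ## red saliency overlay
    img[, , 1] <- pmin(1, img[, , 1] + 0.7 * cams[vw, , ])
    p <- file.path(config$out,
                   sprintf("%s_gradcam_%s.png", molecule_id,
                           viewOrder(tens)[vw]))
    png::writePNG(img, p)
    paths <- c(paths, p)
  }
  w <- scrnForward(bundles[[molecule_id]], st$scrn)$weights
  csv <- file.path(config$out, paste0(molecule_id, "_gates.csv"))
  utils::write.csv(data.frame(id = molecule_id, fingerprint = w[1],
                              graph = w[2], spatial = w[3]),
                   csv, row.names = FALSE)
  invisible(c(paths, csv))
}
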