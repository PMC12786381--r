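## Synthetic fixtures: grammar-generated molecules, planted interaction
## graphs with a stored Bayes-optimal recovery bound, and
## structure-derived scalar endpoints. Everything regenerates
## bit-exactly from (spec, seed); no downloads.

.enantiomerTemplates <- list(
  c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"),
  c("[C@H](F)(Cl)Br", "[C@@H](F)(Cl)Br"),
  c("C[C@H](O)CC", "C[C@@H](O)CC"))

.bicyclicTemplates <- c("c1ccc2ccccc2c1", "C1CCC2CCCCC2C1",
                        "c1ccc2[nH]ccc2c1", "c1ccc2OCCc2c1")

.benzeneSubstituents <- c("C", "O", "N", "F", "Cl", "Br", "CC", "OC",
                          "C(=O)O", "N(C)C", "CO")

randomChainSmiles <- function() {
  len <- sample(3:8, 1)
  atoms <- sample(c("C", "C", "C", "C", "O", "N"), len, replace = TRUE)
  ## avoid O-O / N-N / O-N adjacencies (keeps valence chemistry tame)
  for (k in seq_len(len - 1))
    if (atoms[k] != "C" && atoms[k + 1] != "C") atoms[k + 1] <- "C"
  paste(atoms, collapse = "")
}

randomBenzeneSmiles <- function() {
  ns <- sample(0:2, 1)
  if (ns == 0) return("c1ccccc1")
  subs <- sample(.benzeneSubstituents, ns, replace = TRUE)
  if (ns == 1) sprintf("%sc1ccccc1", subs[1])
  else sprintf("%sc1ccc(%s)cc1", subs[1], subs[2])
}

#' Generate a synthetic molecule set
#'
#' Draws n valid SMILES from a seeded template grammar: heteroatom
#' chains (alkanes/ethers/amines), substituted benzenes, fused
#' bicyclics and stereocenter templates. All molecules parse and embed.
#' With \code{include_enantiomer_pairs} the first two entries are an
#' R/S pair differing only in their stereo descriptors.
#'
#' @param n number of molecules (>= 1).
#' @param seed RNG seed; identical (n, seed) give identical output.
#' @param include_enantiomer_pairs force at least one enantiomer pair.
#' @return data.frame(id, smiles).
#' @export
genMoleculeSet <- function(n, seed = 0L, include_enantiomer_pairs = FALSE) {
  stopifnot(n >= 1)
  withSeed(seed, {
    out <- character(0)
    if (include_enantiomer_pairs && n >= 2) {
      pair <- .enantiomerTemplates[[sample(length(.enantiomerTemplates), 1)]]
      out <- pair
    }
    while (length(out) < n) {
      kind <- sample(c("chain", "benzene", "bicyclic", "stereo"), 1,
                     prob = c(0.4, 0.3, 0.2, 0.1))
      smi <- switch(kind,
        chain = randomChainSmiles(),
        benzene = randomBenzeneSmiles(),
        bicyclic = sample(.bicyclicTemplates, 1),
        stereo = sample(unlist(.enantiomerTemplates), 1))
      out <- c(out, smi)
    }
    data.frame(id = sprintf("MOL%03d", seq_len(n)),
               smiles = out[seq_len(n)], stringsAsFactors = FALSE)
  })
}

#' Specification of a planted interaction graph
#'
#' @param n_drugs,n_partners entity counts (>= 2).
#' @param latent_dim dimension of the planted latent factors.
#' @param noise_sd standard deviation of logit noise.
#' @param edge_logit_scale scale on the latent inner product.
#' @param partner_dim dimension of emitted partner feature vectors.
#' @param d2 drug graph-embedding dimension the signal is injected into.
#' @param seed generation seed.
#' @return spec list.
#' @export
plantedGraphSpec <- function(n_drugs = 50L, n_partners = 40L,
                             latent_dim = 8L, noise_sd = 0,
                             edge_logit_scale = 3, partner_dim = 64L,
                             d2 = 64L, seed = 0L) {
  stopifnot(n_drugs >= 2, n_partners >= 2, latent_dim >= 1, noise_sd >= 0)
  list(n_drugs = as.integer(n_drugs), n_partners = as.integer(n_partners),
       latent_dim = as.integer(latent_dim), noise_sd = noise_sd,
       edge_logit_scale = edge_logit_scale,
       partner_dim = as.integer(partner_dim), d2 = as.integer(d2),
       seed = as.integer(seed))
}

#' Generate a planted interaction graph fixture
#'
#' Latent factors u_i, v_j ~ N(0, 1)^latent_dim; edge labels are
#' Bernoulli with P(edge) = sigmoid(scale * <u_i, v_j> + noise). The
#' drug factors are emitted as a linear signal for injection into the
#' drug graph-embedding channel (\code{drug_signal}), and partner
#' feature vectors are a seeded linear image of v_j, so the planted
#' structure is recoverable by the learnable pipeline. The
#' Bayes-optimal AUC (true logits scored against the sampled labels) is
#' stored in the manifest and upper-bounds any model's achievable AUC.
#'
#' @param spec a \code{\link{plantedGraphSpec}}.
#' @return manifest list (spec, ids, factors, edges, partner_features,
#'   drug_signal, bayes_auc, spec_hash).
#' @export
genInteractionGraph <- function(spec = plantedGraphSpec()) {
  if (spec$edge_logit_scale == 0)
    warning("edge_logit_scale is 0: planted signal absent")
  withSeed(spec$seed, {
    n <- spec$n_drugs; m <- spec$n_partners; k <- spec$latent_dim
    u <- matrix(rnorm(n * k), n, k)
    v <- matrix(rnorm(m * k), m, k)
    logits <- spec$edge_logit_scale * tcrossprod(u, v)
    if (spec$noise_sd > 0)
      logits <- logits + matrix(rnorm(n * m, sd = spec$noise_sd), n, m)
    P <- sigmoid(logits)
    Y <- matrix(rbinom(n * m, 1, as.vector(P)), n, m)
    drugIds <- sprintf("MOL%03d", seq_len(n))
    partnerIds <- sprintf("PRT%03d", seq_len(m))
    ## seeded linear maps carrying the latent factors into feature space
    Bu <- matrix(rnorm(k * spec$d2, sd = 1 / sqrt(k)), k, spec$d2)
    Bv <- matrix(rnorm(k * spec$partner_dim, sd = 1 / sqrt(k)), k,
                 spec$partner_dim)
    drugSignal <- u %*% Bu
    partnerFeatures <- v %*% Bv
    rownames(drugSignal) <- drugIds
    rownames(partnerFeatures) <- partnerIds
    edges <- data.frame(
      drug = rep(drugIds, times = m),
      partner = rep(partnerIds, each = n),
      label = as.integer(as.vector(Y)))
    bayes <- aucRank(as.vector(logits), as.vector(Y))
    manifest <- list(spec = spec, drug_ids = drugIds,
                     partner_ids = partnerIds, u = u, v = v,
                     edges = edges, drug_signal = drugSignal,
                     partner_features = partnerFeatures,
                     bayes_auc = bayes, spec_hash = configHash(spec))
    manifest
  })
}

#' Structure-derived synthetic toxicity endpoints
#'
#' value = 2 + 0.35 * heavy_atoms - 0.8 * rings + 3 * heteroatom_frac
#' + N(0, noise_sd): a linear function of interpretable descriptors so
#' a regression head can provably recover it; the coefficients are
#' returned in the "coefficients" attribute.
#'
#' @param mols list of parsed \linkS4class{MoleculeRecord}s.
#' @param seed RNG seed for the noise.
#' @param noise_sd noise standard deviation (0 = exact function).
#' @return data.frame(id, value) with attribute "coefficients".
#' @export
genToxicityEndpoints <- function(mols, seed = 0L, noise_sd = 0) {
  coef <- c(intercept = 2, heavy_atoms = 0.35, rings = -0.8,
            hetero_frac = 3)
  desc <- t(vapply(mols, function(mol) {
    g <- heavyGraph(mol)
    na <- length(g$elements); nb <- nrow(g$bonds)
    comps <- graphComponents(na, g$bonds)
    c(na, nb - na + comps, mean(g$elements != "C"))
  }, numeric(3)))
  vals <- coef[1] + desc %*% coef[2:4]
  withSeed(seed, {
    if (noise_sd > 0) vals <- vals + rnorm(length(vals), sd = noise_sd)
    structure(data.frame(id = vapply(mols, molId, character(1)),
                         value = as.vector(vals)),
              coefficients = coef)
  })
}

## connected components of an undirected atom graph
graphComponents <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  if (nrow(bonds) > 0) for (r in seq_len(nrow(bonds))) {
    ra <- find(bonds[r, 1]); rb <- find(bonds[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Write / read a fixture manifest directory
#'
#' Plain-text layout: smiles.tsv, edges.tsv, partner_features.tsv,
#' drug_signal.tsv and manifest.json (spec, seed, hashes, Bayes AUC).
#'
#' @param manifest from \code{\link{genInteractionGraph}}.
#' @param dir output directory (created).
#' @param smiles optional data.frame(id, smiles) to include.
#' @return the directory, invisibly.
#' @export
writeFixtureManifest <- function(manifest, dir, smiles = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(smiles))
    write.table(smiles, file.path(dir, "smiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(manifest$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = rownames(manifest$partner_features),
                         manifest$partner_features),
              file.path(dir, "partner_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = rownames(manifest$drug_signal),
                         manifest$drug_signal),
              file.path(dir, "drug_signal.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(spec = manifest$spec, bayes_auc = manifest$bayes_auc,
               spec_hash = manifest$spec_hash,
               u = manifest$u, v = manifest$v)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeFixtureManifest
#' @export
readFixtureManifest <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  edges <- read.table(file.path(dir, "edges.tsv"), sep = "\t",
                      header = TRUE, colClasses = c("character",
                                                    "character", "integer"))
  pf <- read.table(file.path(dir, "partner_features.tsv"), sep = "\t",
                   header = TRUE)
  ds <- read.table(file.path(dir, "drug_signal.tsv"), sep = "\t",
                   header = TRUE)
  pfm <- as.matrix(pf[, -1]); rownames(pfm) <- pf$id
  dsm <- as.matrix(ds[, -1]); rownames(dsm) <- ds$id
  list(spec = meta$spec, drug_ids = ds$id, partner_ids = pf$id,
       u = meta$u, v = meta$v, edges = edges, drug_signal = dsm,
       partner_features = pfm, bayes_auc = meta$bayes_auc,
       spec_hash = meta$spec_hash)
}
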