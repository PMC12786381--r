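## 1D/2D drug featurization: SMILES parsing, MMFF94s conformers,
## fingerprints and the graph-convolutional embedding.

## OpenBabel accepts some malformed SMILES (e.g. a dangling branch "C(")
## by silently repairing them, so balance is checked here first.
checkSmilesSyntax <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
    stopMv("ParseError", "unbalanced parentheses in SMILES '%s'", smiles)
  bdepth <- cumsum((chars == "[") - (chars == "]"))
  if (length(bdepth) && (any(bdepth < 0) || bdepth[length(bdepth)] != 0))
    stopMv("ParseError", "unbalanced brackets in SMILES '%s'", smiles)
  invisible(TRUE)
}

obCanonicalSmiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) "")
  can <- sub("[\t\n ].*$", "", out)
  if (!nzchar(can))
    stopMv("ParseError", "unparsable SMILES '%s'", smiles)
  can
}

## Formal charge from bracket atoms of a canonical SMILES.
smilesFormalCharge <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  total <- 0L
  for (b in brackets) {
    m <- regmatches(b, regexpr("[+-][0-9]*(?=\\]$)", b, perl = TRUE))
    if (length(m) == 0) {
      ## runs like ++ or --
      m <- regmatches(b, regexpr("[+]+(?=\\]$)|[-]+(?=\\]$)", b, perl = TRUE))
      if (length(m)) total <- total + nchar(m) * if (grepl("\\+", m)) 1L else -1L
      next
    }
    sign <- if (substr(m, 1, 1) == "+") 1L else -1L
    mag <- sub("^[+-]", "", m)
    total <- total + sign * if (nzchar(mag)) as.integer(mag) else 1L
  }
  total
}

## Minimal V2000 MOL-block reader: counts line, atom lines, bond lines,
## optional "> <tag>" data fields. Returns NULL on malformed input.
parseMolblock <- function(lines) {
  if (length(lines) < 4) return(NULL)
  na <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) return(NULL)
  if (length(lines) < 4 + na + nb) return(NULL)
  al <- lines[4 + seq_len(na)]
  coords <- cbind(as.numeric(substr(al, 1, 10)),
                  as.numeric(substr(al, 11, 20)),
                  as.numeric(substr(al, 21, 30)))
  elements <- trimws(substr(al, 31, 34))
  bonds <- matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(i = as.integer(substr(bl, 1, 3)),
                   j = as.integer(substr(bl, 4, 6)),
                   order = as.integer(substr(bl, 7, 9)))
  }
  if (anyNA(coords) || anyNA(bonds) || any(!nzchar(elements))) return(NULL)
  ## data fields ("> <tag>" then value lines until blank)
  data <- list()
  tagLines <- grep("^> *<", lines)
  for (t in tagLines) {
    tag <- sub("^> *<([^>]*)>.*$", "\\1", lines[t])
    data[[tag]] <- lines[t + 1]
  }
  list(title = lines[1], elements = elements, coords = coords,
       bonds = bonds, data = data)
}

## Split an SDF file/text into MOL blocks on "$$$$".
splitSdfBlocks <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) return(list(lines))
  starts <- c(1, head(ends, -1) + 1)
  mapply(function(s, e) lines[s:(e - 1)], starts, ends, SIMPLIFY = FALSE)
}

## Heavy-atom graph (elements + bond table) for a SMILES, via OpenBabel.
smilesHeavyGraph <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) "")
  g <- parseMolblock(strsplit(txt, "\n")[[1]])
  if (is.null(g))
    stopMv("ParseError", "unparsable SMILES '%s'", smiles)
  g
}

#' Parse a SMILES string into a MoleculeRecord
#'
#' Canonicalizes the SMILES (OpenBabel canonical form) and extracts the
#' heavy-atom element/bond graph. No conformer is generated; see
#' \code{\link{embedConformer}}.
#'
#' @param smiles a single SMILES string.
#' @param id molecule identifier.
#' @return a \linkS4class{MoleculeRecord} with empty coordinates.
#' @examples
#' mol <- parseSmiles("CCO", "ethanol")
#' canonicalSmiles(mol)
#' @export
parseSmiles <- function(smiles, id = "mol") {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    stopMv("ParseError", "SMILES must be a non-empty string")
  checkSmilesSyntax(smiles)
  can <- obCanonicalSmiles(smiles)
  g <- smilesHeavyGraph(can)
  new("MoleculeRecord", id = as.character(id), smiles = can,
      elements = g$elements, bonds = g$bonds,
      charge = smilesFormalCharge(can))
}

embedScriptPath <- function() {
  p <- system.file("python", "embed_conformers.py", package = "molviews")
  if (!nzchar(p))       # during development, before installation
    p <- file.path("inst", "python", "embed_conformers.py")
  p
}

#' Generate MMFF94s-minimized 3D conformers
#'
#' Adds hydrogens, builds a seeded distance-geometry (ETKDG) 3D
#' embedding and minimizes it with the MMFF94s force field; identical
#' seeds reproduce bitwise-identical coordinates, different seeds may
#' yield different (valid) conformers. The minimized force-field energy
#' (kcal/mol) is recorded. \code{embedConformerBatch} embeds a list of
#' molecules in one pass, which amortizes the per-call cost.
#'
#' @param mol a parsed \linkS4class{MoleculeRecord}.
#' @param seed integer embedding seed.
#' @return \code{embedConformer}: the record with hydrogens, coordinates
#'   and energy filled in; \code{embedConformerBatch}: a named list of
#'   records, with failures reported via \code{attr(, "failed")}.
#' @export
embedConformer <- function(mol, seed = 0L) {
  out <- embedConformerBatch(list(mol), seed)
  if (length(out) == 0)
    stopMv("ConformerError", "3D embedding failed for '%s' (%s): %s",
           mol@id, mol@smiles,
           paste(attr(out, "failed")$reason, collapse = "; "))
  out[[1]]
}

#' @rdname embedConformer
#' @param mols list of parsed \linkS4class{MoleculeRecord}s.
#' @export
embedConformerBatch <- function(mols, seed = 0L) {
  if (is(mols, "MoleculeRecord")) mols <- list(mols)
  stopifnot(all(vapply(mols, is, logical(1), "MoleculeRecord")))
  tmp <- tempfile(fileext = ".tsv"); sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp, sdf)), add = TRUE)
  writeLines(vapply(mols, function(m) paste0(m@id, "\t", m@smiles),
                    character(1)), tmp)
  res <- suppressWarnings(
    system2("python", c(shQuote(embedScriptPath()), shQuote(tmp),
                        as.integer(seed), shQuote(sdf)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stopMv("ConformerError", "conformer generation failed: %s",
           paste(res, collapse = " | "))
  failLines <- grep("^FAIL\t", res, value = TRUE)
  failed <- if (length(failLines)) {
    parts <- strsplit(failLines, "\t")
    data.frame(id = vapply(parts, `[`, character(1), 2),
               reason = vapply(parts, `[`, character(1), 3))
  } else data.frame(id = character(0), reason = character(0))
  byId <- stats::setNames(mols, vapply(mols, molId, character(1)))
  out <- list()
  if (file.exists(sdf) && file.size(sdf) > 0) {
    for (b in splitSdfBlocks(readLines(sdf, warn = FALSE))) {
      g <- parseMolblock(b)
      if (is.null(g) || !all(is.finite(g$coords))) next
      id <- trimws(g$title)
      src <- byId[[id]]
      energy <- suppressWarnings(as.numeric(g$data$energy_kcal_mol))
      out[[id]] <- new("MoleculeRecord", id = id,
                       smiles = if (!is.null(src)) src@smiles
                                else g$data$smiles,
                       elements = g$elements, coords = g$coords,
                       bonds = g$bonds,
                       charge = if (!is.null(src)) src@charge else 0L,
                       conformerEnergy = energy)
    }
  }
  structure(out, failed = failed)
}

## Restrict a record's atom graph to heavy atoms (indices remapped).
heavyGraph <- function(mol) {
  keep <- which(mol@elements != "H")
  map <- integer(length(mol@elements)); map[keep] <- seq_along(keep)
  b <- mol@bonds
  if (nrow(b) > 0) {
    hb <- b[mol@elements[b[, 1]] != "H" & mol@elements[b[, 2]] != "H", ,
            drop = FALSE]
    hb[, 1] <- map[hb[, 1]]; hb[, 2] <- map[hb[, 2]]
  } else hb <- b
  list(elements = mol@elements[keep], bonds = hb)
}

foldBits <- function(positions, n_bits) {
  v <- integer(n_bits)
  if (length(positions)) v[((positions - 1L) %% n_bits) + 1L] <- 1L
  v
}

## Topological torsion fingerprint: all 4-atom simple bond paths i-j-k-l,
## atom invariant = (element, heavy degree), path read in the
## lexicographically smaller direction, hashed onto n_bits positions.
torsionBits <- function(elements, bonds, n_bits) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(bonds) > 0)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  deg <- lengths(adj)
  inv <- paste0(elements, deg)
  v <- integer(n_bits)
  for (j in seq_len(n)) for (k in adj[[j]]) {
    if (j >= k) next                      # each central bond once
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next                    # no 4-rings traversed as torsions
      fwd <- paste(inv[c(i, j, k, l)], collapse = "-")
      rev <- paste(inv[c(l, k, j, i)], collapse = "-")
      key <- if (fwd <= rev) fwd else rev
      v[(fnv1a32(key) %% n_bits) + 1L] <- 1L
    }
  }
  v
}

#' Compute a binary molecular fingerprint
#'
#' Supported kinds: \code{"morgan"} (extended-connectivity, radius 2 =
#' ECFP4, folded to \code{n_bits}), \code{"maccs"} (the fixed 166-key
#' structural catalog; \code{n_bits} is ignored) and
#' \code{"topological_torsion"} (hashed 4-atom bond paths). Fingerprints
#' are computed from the canonical SMILES, so all spellings of one
#' molecule give identical bits.
#'
#' @param mol a \linkS4class{MoleculeRecord}.
#' @param kind fingerprint type.
#' @param n_bits vector length for hashed kinds (default 1024).
#' @return integer 0/1 vector with attributes \code{kind} and \code{n_bits}.
#' @export
computeFingerprint <- function(mol,
                               kind = c("morgan", "maccs",
                                        "topological_torsion"),
                               n_bits = 1024L) {
  stopifnot(is(mol, "MoleculeRecord"))
  kind <- tryCatch(match.arg(kind),
                   error = function(e)
                     stopMv("ConfigError", "unsupported fingerprint kind '%s'",
                            paste(kind, collapse = ",")))
  if (kind %in% c("morgan", "maccs")) {
    obmol <- ChemmineOB::forEachMol("SMILES", mol@smiles, identity)
    raw <- ChemmineOB::fingerprint_OB(
      obmol, if (kind == "morgan") "ECFP4" else "MACCS")
    bits <- if (kind == "morgan") foldBits(which(raw != 0), as.integer(n_bits))
            else as.integer(raw[seq_len(166)] != 0)
  } else {
    g <- heavyGraph(mol)
    bits <- torsionBits(g$elements, g$bonds, as.integer(n_bits))
  }
  structure(bits, kind = kind, n_bits = length(bits))
}

defaultGraphEncoderParams <- function(d2 = 64L, rounds = 2L, hidden = 32L,
                                      seed = 1L, readout = "sum") {
  list(d2 = as.integer(d2), rounds = as.integer(rounds),
       hidden = as.integer(hidden), seed = as.integer(seed),
       readout = match.arg(readout, c("sum", "mean")))
}

.graphElems <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

graphAtomFeatures <- function(elements, bonds) {
  n <- length(elements)
  deg <- integer(n)
  if (nrow(bonds) > 0) {
    t1 <- tabulate(bonds[, 1], n); t2 <- tabulate(bonds[, 2], n)
    deg <- t1 + t2
  }
  elemIdx <- match(elements, .graphElems)
  feat <- matrix(0, n, length(.graphElems) + 1 + 4)
  for (a in seq_len(n)) {
    if (is.na(elemIdx[a])) feat[a, length(.graphElems) + 1] <- 1
    else feat[a, elemIdx[a]] <- 1
    feat[a, length(.graphElems) + 1 + min(deg[a] + 1, 4)] <- 1
  }
  feat
}

#' Graph-convolutional molecular embedding (2D modality)
#'
#' A compact atom/bond message-passing encoder: one-hot atom features
#' (element, heavy degree) and bond-order features are linearly embedded,
#' then updated for \code{rounds} rounds with tanh units, each atom
#' aggregating its neighbours and incident bond features by summation; a
#' symmetric sum (or mean) readout followed by a linear projection yields
#' the d2-dimensional embedding. Weights are drawn once from a seeded
#' Glorot initializer, so the map is deterministic in
#' (canonical molecule, seed) and invariant to atom-index permutation.
#'
#' @param mol a \linkS4class{MoleculeRecord}.
#' @param params see \code{defaultGraphEncoderParams}; fields d2, rounds,
#'   hidden, seed, readout.
#' @return numeric vector of length \code{params$d2} with attribute
#'   \code{config_hash}.
#' @export
computeGraphEmbedding <- function(mol, params = defaultGraphEncoderParams()) {
  stopifnot(is(mol, "MoleculeRecord"))
  g <- heavyGraph(mol)
  n <- length(g$elements)
  feat <- graphAtomFeatures(g$elements, g$bonds)
  nb <- nrow(g$bonds)
  bfeat <- matrix(0, nb, 3)
  if (nb > 0) bfeat[cbind(seq_len(nb), pmin(g$bonds[, 3], 3))] <- 1
  W <- withSeed(params$seed, {
    h <- params$hidden
    list(atom = xavierMatrix(h, ncol(feat)),
         bond = xavierMatrix(h, 3),
         self = replicate(params$rounds, xavierMatrix(h, h), simplify = FALSE),
         nbr  = replicate(params$rounds, xavierMatrix(h, h), simplify = FALSE),
         be   = replicate(params$rounds, xavierMatrix(h, h), simplify = FALSE),
         out  = xavierMatrix(params$d2, h))
  })
  hA <- feat %*% t(W$atom)                            # n x hidden
  hB <- if (nb > 0) bfeat %*% t(W$bond) else matrix(0, 0, params$hidden)
  for (r in seq_len(params$rounds)) {
    nbrSum <- matrix(0, n, params$hidden)
    bondSum <- matrix(0, n, params$hidden)
    if (nb > 0) for (e in seq_len(nb)) {
      i <- g$bonds[e, 1]; j <- g$bonds[e, 2]
      nbrSum[i, ] <- nbrSum[i, ] + hA[j, ]
      nbrSum[j, ] <- nbrSum[j, ] + hA[i, ]
      bondSum[i, ] <- bondSum[i, ] + hB[e, ]
      bondSum[j, ] <- bondSum[j, ] + hB[e, ]
    }
    hA <- tanh(hA %*% t(W$self[[r]]) + nbrSum %*% t(W$nbr[[r]]) +
                 bondSum %*% t(W$be[[r]]))
  }
  pooled <- colSums(hA)
  if (params$readout == "mean") pooled <- pooled / n
  vec <- as.vector(W$out %*% pooled)
  structure(vec, config_hash = configHash(params))
}

#' Read a SMILES list file (TSV: id &lt;tab&gt; smiles)
#' @param path file path.
#' @return data.frame with columns id, smiles.
#' @export
readSmilesFile <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "smiles"),
                          colClasses = "character", quote = "")
  if (nrow(df) > 0 && identical(tolower(df$id[1]), "id"))
    df <- df[-1, , drop = FALSE]   # header line present
  df
}

#' Write / read conformers as SDF
#' @param mols list of MoleculeRecord with conformers.
#' @param path SDF file path.
#' @export
writeMoleculeSdf <- function(mols, path) {
  if (is(mols, "MoleculeRecord")) mols <- list(mols)
  con <- file(path, "w"); on.exit(close(con))
  for (mol in mols) {
    if (nrow(mol@coords) == 0)
      stopMv("ConformerError", "molecule '%s' has no conformer", mol@id)
    na <- length(mol@elements); nb <- nrow(mol@bonds)
    writeLines(c(mol@id, "  molviews", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (a in seq_len(na))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         mol@coords[a, 1], mol@coords[a, 2], mol@coords[a, 3],
                         mol@elements[a]), con)
    for (b in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", mol@bonds[b, 1],
                         mol@bonds[b, 2], mol@bonds[b, 3]), con)
    writeLines(c("M  END",
                 "> <energy_kcal_mol>", as.character(mol@conformerEnergy), "",
                 "> <smiles>", mol@smiles, "", "$$$$"), con)
  }
  invisible(path)
}

#' @rdname writeMoleculeSdf
#' @param path SDF file path.
#' @export
readMoleculeSdf <- function(path) {
  blocks <- splitSdfBlocks(readLines(path, warn = FALSE))
  out <- list()
  for (b in blocks) {
    g <- parseMolblock(b)
    if (is.null(g)) next
    smiles <- if (!is.null(g$data$smiles)) g$data$smiles
              else paste(g$elements[g$elements != "H"], collapse = "")
    energy <- if (!is.null(g$data$energy_kcal_mol))
      suppressWarnings(as.numeric(g$data$energy_kcal_mol)) else NA_real_
    out[[length(out) + 1]] <-
      new("MoleculeRecord", id = trimws(g$title), smiles = smiles,
          elements = g$elements, coords = g$coords, bonds = g$bonds,
          charge = 0L, conformerEnergy = energy)
  }
  out
}
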