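## Bemis-Murcko scaffolds: extraction, leakage-free splitting and
## diversity statistics.

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively strips terminal (degree-1) heavy atoms until none
#' remain, leaving the ring systems plus their linkers; the core is
#' re-canonicalized so that molecules sharing a framework map to the
#' same scaffold SMILES. Acyclic molecules have an empty scaffold ("")
#' and are treated as one shared scaffold group.
#'
#' @param mol a \linkS4class{MoleculeRecord} (or SMILES string).
#' @return scaffold SMILES ("" for acyclic molecules).
#' @export
murckoScaffold <- function(mol) {
  if (is.character(mol)) mol <- parseSmiles(mol)
  g <- heavyGraph(mol)
  n <- length(g$elements)
  keep <- rep(TRUE, n)
  bonds <- g$bonds
  repeat {
    deg <- integer(n)
    if (nrow(bonds) > 0) {
      deg <- tabulate(bonds[, 1], n) + tabulate(bonds[, 2], n)
    }
    term <- which(keep & deg <= 1)
    ## isolated kept atoms (deg 0) only count as terminal if anything
    ## else remains connected; stripping order is degree-1 first
    term <- term[deg[term] == 1 | sum(keep) > 0]
    if (length(term) == 0 || !any(keep)) break
    keep[term] <- FALSE
    if (!any(keep)) break
    bonds <- bonds[keep[bonds[, 1]] & keep[bonds[, 2]], , drop = FALSE]
    if (all(tabulate(bonds[, 1], n) + tabulate(bonds[, 2], n) != 1)) break
  }
  if (!any(keep) || nrow(bonds) == 0) return("")
  idx <- which(keep)
  map <- integer(n); map[idx] <- seq_along(idx)
  sub <- bonds
  sub[, 1] <- map[sub[, 1]]; sub[, 2] <- map[sub[, 2]]
  canonicalizeFragment(g$elements[idx], sub)
}

## Canonical SMILES of an element/bond fragment via a synthetic MOL block.
canonicalizeFragment <- function(elements, bonds) {
  na <- length(elements); nb <- nrow(bonds)
  lines <- c("fragment", "  molviews", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     0, 0, 0, elements),
             if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0",
                                 bonds[, 1], bonds[, 2], bonds[, 3]),
             "M  END", "$$$$")
  txt <- paste(lines, collapse = "\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt)),
    error = function(e) "")
  sub("[\t\n ].*$", "", out)
}

#' Scaffold-disjoint train/test split
#'
#' Groups molecules by Bemis-Murcko scaffold, shuffles the groups with
#' the seed and greedily assigns whole groups to the test set until at
#' least \code{test_frac} of the molecules are held out; train and test
#' scaffold sets are therefore disjoint by construction. If all
#' molecules share one scaffold the split is impossible: everything
#' stays in train and a warning is emitted.
#'
#' @param mols list of \linkS4class{MoleculeRecord}s (or SMILES vector).
#' @param test_frac fraction of molecules to hold out (0 < f < 1).
#' @param seed RNG seed for the group shuffle.
#' @return list(train_ids, test_ids, scaffold_map).
#' @export
scaffoldSplit <- function(mols, test_frac = 0.2, seed = 0L) {
  stopifnot(test_frac > 0, test_frac < 1)
  if (is.character(mols))
    mols <- lapply(seq_along(mols), function(i)
      parseSmiles(mols[i], paste0("mol", i)))
  ids <- vapply(mols, molId, character(1))
  scaffolds <- vapply(mols, murckoScaffold, character(1))
  names(scaffolds) <- ids
  groups <- split(ids, scaffolds)
  if (length(groups) < 2) {
    warning("all molecules share one scaffold; split impossible, ",
            "everything assigned to train")
    return(list(train_ids = ids, test_ids = character(0),
                scaffold_map = scaffolds))
  }
  withSeed(seed, {
    ord <- sample(length(groups))
    target <- test_frac * length(ids)
    testIds <- character(0)
    for (gi in ord) {
      if (length(testIds) >= target) break
      testIds <- c(testIds, groups[[gi]])
    }
    list(train_ids = setdiff(ids, testIds), test_ids = testIds,
         scaffold_map = scaffolds)
  })
}

#' Scaffold diversity statistics
#'
#' Diversity ratio = unique scaffolds / valid molecules; Shannon
#' entropy (natural log) of the scaffold frequency distribution.
#'
#' @param mols list of MoleculeRecords, SMILES vector, or a character
#'   vector of pre-computed scaffolds (attribute-free strings).
#' @param scaffolds set TRUE if \code{mols} already holds scaffold
#'   strings.
#' @return list(n_valid, n_unique, diversity_ratio, shannon_entropy).
#' @export
scaffoldDiversity <- function(mols, scaffolds = FALSE) {
  sc <- if (isTRUE(scaffolds)) as.character(mols)
        else {
          if (is.character(mols))
            mols <- lapply(seq_along(mols), function(i)
              parseSmiles(mols[i], paste0("mol", i)))
          vapply(mols, murckoScaffold, character(1))
        }
  stopifnot(length(sc) >= 1)
  p <- as.numeric(table(sc)) / length(sc)
  list(n_valid = length(sc), n_unique = length(unique(sc)),
       diversity_ratio = length(unique(sc)) / length(sc),
       shannon_entropy = -sum(p * log(p)))
}
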