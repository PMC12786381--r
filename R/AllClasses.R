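## Central S4 classes.

#' MoleculeRecord: a parsed molecule with optional 3D conformer
#'
#' Holds a canonicalized SMILES, the atom/bond graph and, once
#' \code{\link{embedConformer}} has run, MMFF94s-minimized 3D coordinates
#' (hydrogens included) plus the post-minimization force-field energy.
#' Before embedding, \code{elements}/\code{bonds} describe the heavy-atom
#' graph from the SMILES parse and \code{coords} has zero rows.
#'
#' @slot id character molecule identifier.
#' @slot smiles canonical SMILES string.
#' @slot elements character vector of atomic symbols.
#' @slot coords N x 3 numeric matrix of positions in Angstrom (0 rows until
#'   a conformer is embedded).
#' @slot bonds integer matrix with columns \code{i}, \code{j}, \code{order}.
#' @slot charge integer total formal charge.
#' @slot conformerEnergy numeric MMFF94s energy in kcal/mol (NA until
#'   minimized).
#' @export
setClass("MoleculeRecord",
  representation(id = "character", smiles = "character",
                 elements = "character", coords = "matrix",
                 bonds = "matrix", charge = "integer",
                 conformerEnergy = "numeric"),
  prototype(coords = matrix(numeric(0), 0, 3), charge = 0L,
            conformerEnergy = NA_real_))

setValidity("MoleculeRecord", function(object) {
  n <- length(object@elements)
  if (n < 1) return("molecule must have at least one atom")
  if (nrow(object@coords) > 0) {
    if (nrow(object@coords) != n) return("coords rows must match atom count")
    if (ncol(object@coords) != 3) return("coords must be N x 3")
    if (!all(is.finite(object@coords))) return("coords must be finite")
  }
  if (nrow(object@bonds) > 0) {
    if (ncol(object@bonds) != 3) return("bonds must have columns i, j, order")
    if (max(object@bonds[, 1:2]) > n || min(object@bonds[, 1:2]) < 1)
      return("bond indices out of range")
  }
  TRUE
})

#' ViewTensor: six orthogonal RGBA renderings of one molecule
#'
#' Dense numeric array of shape 4 x 6 x H x W, values in [0, 1]: four color
#' channels (CPK red, green, blue + alpha/occupancy) by six orthographic
#' views in the fixed order front, right, back, bottom, top, left.
#'
#' @slot data 4-dimensional numeric array, 4 x 6 x H x W.
#' @slot viewOrder character(6), fixed view labels.
#' @export
setClass("ViewTensor",
  representation(data = "array", viewOrder = "character"),
  prototype(viewOrder = c("front", "right", "back", "bottom", "top", "left")))

setValidity("ViewTensor", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a 4-D array")
  if (d[1] != 4) return("first dimension (channels) must be 4")
  if (d[2] != 6) return("second dimension (views) must be 6")
  if (!all(is.finite(object@data))) return("tensor must be finite")
  if (min(object@data) < 0 || max(object@data) > 1)
    return("tensor values must lie in [0, 1]")
  if (!identical(object@viewOrder,
                 c("front", "right", "back", "bottom", "top", "left")))
    return("viewOrder must be front, right, back, bottom, top, left")
  TRUE
})

#' ModalityBundle: the three drug modalities for one molecule
#'
#' @slot id character molecule identifier.
#' @slot x1 numeric binary fingerprint vector (1D modality).
#' @slot x2 numeric graph-convolutional embedding (2D modality).
#' @slot x3 numeric directional spatial feature (3D modality).
#' @export
setClass("ModalityBundle",
  representation(id = "character", x1 = "numeric", x2 = "numeric",
                 x3 = "numeric"))

setValidity("ModalityBundle", function(object) {
  if (!all(is.finite(object@x1), is.finite(object@x2), is.finite(object@x3)))
    return("all modality vectors must be finite")
  if (length(object@x1) < 1 || length(object@x2) < 1 || length(object@x3) < 1)
    return("modality vectors must be non-empty")
  TRUE
})

#' InteractionGraph: drugs, partner entities and their labelled links
#'
#' Adjacency is over the n + m node set (drugs first), symmetric, without
#' self-edges; self-loops are added only inside the GCN normalization.
#' Node features follow the block layout: drug rows carry the fused drug
#' embedding in the first \code{fd} columns and zeros in the remaining
#' \code{ft}; partner rows the reverse.
#'
#' @slot task one of "dti", "ddi", "dmi".
#' @slot drugIds character(n).
#' @slot partnerIds character(m) (equal to drugIds for "ddi").
#' @slot adjacency symmetric sparse 0/1 Matrix over n + m nodes.
#' @slot labels n x m 0/1 matrix of known interaction labels.
#' @slot features (n + m) x (fd + ft) numeric node-feature matrix.
#' @slot fd integer drug-feature width.
#' @slot ft integer partner-feature width.
#' @export
setClass("InteractionGraph",
  representation(task = "character", drugIds = "character",
                 partnerIds = "character", adjacency = "Matrix",
                 labels = "matrix", features = "matrix",
                 fd = "integer", ft = "integer"))

setValidity("InteractionGraph", function(object) {
  n <- length(object@drugIds); m <- length(object@partnerIds)
  if (!object@task %in% c("dti", "ddi", "dmi")) return("unknown task")
  if (object@task == "ddi" && !identical(object@drugIds, object@partnerIds))
    return("ddi requires partner set == drug set")
  nn <- if (object@task == "ddi") n else n + m
  if (!all(dim(object@adjacency) == c(nn, nn)))
    return("adjacency dimension mismatch")
  if (max(abs(object@adjacency - Matrix::t(object@adjacency))) > 0)
    return("adjacency must be symmetric")
  if (any(Matrix::diag(object@adjacency) != 0))
    return("adjacency must have no self-edges")
  if (!all(dim(object@labels) == c(n, m))) return("label matrix mismatch")
  if (nrow(object@features) != nn) return("feature rows must match node count")
  if (ncol(object@features) != object@fd + object@ft)
    return("feature width must equal fd + ft")
  TRUE
})

setMethod("show", "MoleculeRecord", function(object) {
  cat(sprintf("MoleculeRecord '%s': %s\n", object@id, object@smiles))
  cat(sprintf("  %d atoms, %d bonds, charge %+d%s\n",
              length(object@elements), nrow(object@bonds), object@charge,
              if (nrow(object@coords) > 0)
                sprintf(", conformer E = %.3f kcal/mol",
                        object@conformerEnergy)
              else ", no conformer"))
})

setMethod("show", "ViewTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("ViewTensor: 4 channels x 6 views x %d x %d px (%s)\n",
              d[3], d[4], paste(object@viewOrder, collapse = ", ")))
})

setMethod("show", "ModalityBundle", function(object) {
  cat(sprintf("ModalityBundle '%s': x1[%d] x2[%d] x3[%d]\n", object@id,
              length(object@x1), length(object@x2), length(object@x3)))
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf("InteractionGraph (%s): %d drugs, %d partners, %d edges\n",
              object@task, length(object@drugIds), length(object@partnerIds),
              Matrix::nnzero(object@adjacency) / 2))
})
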