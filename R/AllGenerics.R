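## Generics and accessors (slot access stays internal).

#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @export
setGeneric("conformerEnergy", function(x) standardGeneric("conformerEnergy"))
#' @export
setGeneric("viewData", function(x) standardGeneric("viewData"))
#' @export
setGeneric("viewOrder", function(x) standardGeneric("viewOrder"))
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @export
setGeneric("interactionLabels", function(x) standardGeneric("interactionLabels"))
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @export
setGeneric("partnerIds", function(x) standardGeneric("partnerIds"))
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' Accessors for MoleculeRecord, ViewTensor and InteractionGraph
#'
#' @param x a \linkS4class{MoleculeRecord}, \linkS4class{ViewTensor},
#'   \linkS4class{ModalityBundle} or \linkS4class{InteractionGraph}.
#' @return the corresponding component: id, canonical SMILES, element
#'   symbols, N x 3 coordinate matrix, bond table, force-field energy,
#'   the 4 x 6 x H x W view array, view labels, adjacency, label matrix,
#'   node-feature matrix, id vectors, or task name.
#' @name accessors
#' @aliases molId canonicalSmiles atomElements atomCoords bondTable
#'   conformerEnergy viewData viewOrder adjacency interactionLabels
#'   nodeFeatures drugIds partnerIds taskType
NULL

#' @rdname accessors
#' @export
setMethod("molId", "MoleculeRecord", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("molId", "ModalityBundle", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("canonicalSmiles", "MoleculeRecord", function(x) x@smiles)
#' @rdname accessors
#' @export
setMethod("atomElements", "MoleculeRecord", function(x) x@elements)
#' @rdname accessors
#' @export
setMethod("atomCoords", "MoleculeRecord", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("bondTable", "MoleculeRecord", function(x) x@bonds)
#' @rdname accessors
#' @export
setMethod("conformerEnergy", "MoleculeRecord", function(x) x@conformerEnergy)
#' @rdname accessors
#' @export
setMethod("viewData", "ViewTensor", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("viewOrder", "ViewTensor", function(x) x@viewOrder)
#' @rdname accessors
#' @export
setMethod("adjacency", "InteractionGraph", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("interactionLabels", "InteractionGraph", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "InteractionGraph", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("drugIds", "InteractionGraph", function(x) x@drugIds)
#' @rdname accessors
#' @export
setMethod("partnerIds", "InteractionGraph", function(x) x@partnerIds)
#' @rdname accessors
#' @export
setMethod("taskType", "InteractionGraph", function(x) x@task)
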