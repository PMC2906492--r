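#' Accessors for ThermoShift classes
#'
#' `atoms()` returns the atom table of a [ProteinStructure-class];
#' `residues()` its per-residue table (chain, res_seq, icode, res_name, in
#' file order); `sites()` the site table of a [MutationSpec-class];
#' `mutationCount()` its number of sites; `structureModels()` the list of
#' models in a [MutantEnsemble-class]; `modelParams()` the hyperparameter
#' list of a [ThermoModel-class].
#'
#' @param x object to access.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setMethod("residues", "ProteinStructure", function(x) {
  a <- x@atoms
  r <- unique(a[, c("chain", "res_seq", "icode", "res_name", "het")])
  rownames(r) <- NULL
  r
})

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setMethod("sites", "MutationSpec", function(x) x@sites)

#' @rdname accessors
#' @export
setGeneric("mutationCount", function(x) standardGeneric("mutationCount"))

#' @rdname accessors
#' @export
setMethod("mutationCount", "MutationSpec", function(x) nrow(x@sites))

#' @rdname accessors
#' @export
setGeneric("structureModels", function(x) standardGeneric("structureModels"))

#' @rdname accessors
#' @export
setMethod("structureModels", "MutantEnsemble", function(x) x@models)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname accessors
#' @export
setMethod("modelParams", "ThermoModel", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("backgroundMean", function(x) standardGeneric("backgroundMean"))

#' @rdname accessors
#' @export
setMethod("backgroundMean", "BackgroundStats", function(x) x@U)

#' @rdname accessors
#' @export
setGeneric("backgroundSd", function(x) standardGeneric("backgroundSd"))

#' @rdname accessors
#' @export
setMethod("backgroundSd", "BackgroundStats", function(x) x@S)

#' @rdname accessors
#' @export
setGeneric("backgroundPool", function(x) standardGeneric("backgroundPool"))

#' @rdname accessors
#' @export
setMethod("backgroundPool", "BackgroundStats", function(x) x@pool)
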