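#' @import methods
NULL

#' Protein structure
#'
#' An atomic protein structure: an ordered atom table parsed from a PDB file
#' (waters removed, first alternate location retained) or built by
#' [generateToyStructure()]. Atoms carry Cartesian coordinates in Angstrom,
#' chain/residue identity and a backbone flag.
#'
#' @slot id character(1), protein identifier.
#' @slot atoms data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `chain`, `res_seq`, `icode`, `res_name`, `is_backbone`, `het`.
#'
#' @seealso [readPDB()], [writePDB()], [atoms()], [residues()]
#' @export
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    req <- c("name", "element", "x", "y", "z", "chain", "res_seq", "icode",
             "res_name", "is_backbone", "het")
    if (!all(req %in% names(a)))
      return(paste("atoms table missing columns:",
                   paste(setdiff(req, names(a)), collapse = ", ")))
    if (nrow(a) > 0L) {
      if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        return("atom coordinates must be finite")
      if (any(!nzchar(a$element)))
        return("every atom needs a non-empty element symbol")
      if (any(a$res_name %in% WATER_RESNAMES))
        return("water residues must be removed")
    }
    TRUE
  }
)

#' Mutation specification
#'
#' An ordered set of single-residue substitutions defining one mutant.
#' Multi-site mutants are a single `MutationSpec` with several sites.
#'
#' @slot sites data.frame with columns `chain`, `res_seq`, `icode`,
#'   `wt` and `mut` (1-letter amino-acid codes).
#'
#' @seealso [parseMutationSpec()], [formatMutationSpec()]
#' @export
setClass("MutationSpec",
  representation(sites = "data.frame"),
  validity = function(object) {
    s <- object@sites
    req <- c("chain", "res_seq", "icode", "wt", "mut")
    if (!all(req %in% names(s)))
      return("sites table needs chain, res_seq, icode, wt, mut")
    if (nrow(s) < 1L) return("a mutation needs at least one site")
    if (any(s$wt == s$mut)) return("silent mutation: wt equals mut")
    if (!all(s$wt %in% AA1) || !all(s$mut %in% AA1))
      return("amino acids must be one of the 20 standard 1-letter codes")
    key <- paste(s$chain, s$res_seq, s$icode)
    if (anyDuplicated(key)) return("duplicate mutation site")
    TRUE
  }
)

#' Mutant structure ensemble
#'
#' The k stochastic structural models built for one mutant, plus the seed
#' that makes them reproducible.
#'
#' @slot spec the [MutationSpec-class] that was applied.
#' @slot models list of k [ProteinStructure-class] objects.
#' @slot seed integer(1) RNG seed used for the coordinate jitter.
#' @export
setClass("MutantEnsemble",
  representation(spec = "MutationSpec", models = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@models) < 1L) return("k must be >= 1")
    if (!all(vapply(object@models, is, logical(1), "ProteinStructure")))
      return("models must all be ProteinStructure")
    TRUE
  }
)

#' Saturation-mutagenesis background statistics
#'
#' Per-feature mean and population standard deviation over the structural
#' features of all l x 19 single-site mutants of one protein, plus the pooled
#' feature matrix used for percentile lookups.
#'
#' @slot U numeric(29), per-feature mean over the background pool.
#' @slot S numeric(29), per-feature population standard deviation.
#' @slot pool numeric matrix, one row per background model, 29 columns.
#' @slot l integer(1), number of standard residues in the protein.
#' @slot protein_id character(1).
#' @slot seed integer(1).
#' @export
setClass("BackgroundStats",
  representation(U = "numeric", S = "numeric", pool = "matrix",
                 l = "integer", protein_id = "character", seed = "integer"),
  validity = function(object) {
    if (length(object@U) != N_FEATURES || length(object@S) != N_FEATURES)
      return("U and S must have 29 entries")
    if (any(object@S < 0)) return("standard deviations must be >= 0")
    if (ncol(object@pool) != N_FEATURES)
      return("pool must have 29 columns")
    TRUE
  }
)

#' Fitted thermostability model
#'
#' A trained learner: sign classifier (`rf`, `svm`) or ddG regressor
#' (`rfr`, `svr`) over 58-element encoded vectors.
#'
#' @slot params list of hyperparameters (see [thermoParams()]).
#' @slot task character(1), `"classification"` or `"regression"`.
#' @slot fitted list, opaque fitted learner state.
#' @slot feature_dim integer(1), always 58.
#' @slot training_summary list: class counts or ddG range.
#' @export
setClass("ThermoModel",
  representation(params = "list", task = "character", fitted = "list",
                 feature_dim = "integer", training_summary = "list"),
  validity = function(object) {
    if (object@feature_dim != ENCODED_DIM)
      return("feature_dim must be 58")
    if (!object@task %in% c("classification", "regression"))
      return("task must be classification or regression")
    algo <- object@params$algorithm
    ok <- (object@task == "classification" && algo %in% c("rf", "svm")) ||
          (object@task == "regression" && algo %in% c("rfr", "svr"))
    if (!ok) return("task inconsistent with algorithm")
    TRUE
  }
)

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "res_seq", "icode")]))
  cat("ProteinStructure", object@id, "-", nrow(a), "atoms,",
      nres, "residues,", length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "MutationSpec", function(object) {
  cat("MutationSpec:", formatMutationSpec(object), "\n")
})

setMethod("show", "MutantEnsemble", function(object) {
  cat("MutantEnsemble:", formatMutationSpec(object@spec), "- k =",
      length(object@models), "models (seed", object@seed, ")\n")
})

setMethod("show", "BackgroundStats", function(object) {
  cat("BackgroundStats for", object@protein_id, "- l =", object@l,
      "residues,", nrow(object@pool), "background models\n")
})

setMethod("show", "ThermoModel", function(object) {
  cat("ThermoModel:", object@params$algorithm, "(", object@task, ")\n")
  ts <- object@training_summary
  if (!is.null(ts$n)) cat("  trained on", ts$n, "mutants\n")
  if (!is.null(ts$class_counts))
    cat("  class counts:", paste(names(ts$class_counts),
        unlist(ts$class_counts), sep = "=", collapse = ", "), "\n")
  if (!is.null(ts$ddg_range))
    cat("  ddG range:", paste(round(unlist(ts$ddg_range), 2), collapse = " .. "),
        "kcal/mol\n")
})
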