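# Encoding: ensemble averaging, saturation background statistics, and the
# 58-element input vector Z = [V; Y].

# call counter used by tests to assert background caching
.bgEnv <- new.env(parent = emptyenv())
.bgEnv$calls <- 0L

backgroundCallCount <- function(reset = FALSE) {
  n <- .bgEnv$calls
  if (reset) .bgEnv$calls <- 0L
  n
}

#' Average an ensemble of feature vectors
#'
#' Element-wise arithmetic mean of the k per-model feature vectors of one
#' mutant, yielding the summary vector N.
#'
#' @param vectors non-empty list of numeric(29) feature vectors.
#' @return numeric(29).
#' @export
ensembleMean <- function(vectors) {
  if (length(vectors) == 0L) stop("cannot average an empty ensemble")
  lens <- vapply(vectors, length, integer(1))
  if (any(lens != N_FEATURES)) stop("feature vectors must have 29 entries")
  m <- colMeans(do.call(rbind, vectors))
  stats::setNames(m, FEATURE_NAMES)
}

# Features of every model of a MutantEnsemble, as a matrix.
.ensembleFeatureMatrix <- function(ensemble, backend = computeFeatures) {
  do.call(rbind, lapply(structureModels(ensemble), backend))
}

#' Saturation-mutagenesis background statistics of a protein
#'
#' Enumerates all l x 19 single-site mutants of the wild-type structure,
#' builds `k_background` stochastic models for each, computes the 29
#' structural features of every model, and summarises the pooled matrix by
#' its per-feature mean U and population standard deviation S. The pool is
#' retained for percentile lookups by [encodeMutant()]. Deterministic for a
#' fixed seed.
#'
#' @param structure wild-type [ProteinStructure-class] with >= 1 standard
#'   residue.
#' @param k_background models per background mutant (default 1; the
#'   background only estimates means, spreads and ranks).
#' @param seed integer RNG seed.
#' @param chains optional chain restriction.
#' @param backend feature backend, a `function(structure) -> numeric(29)`.
#' @return A [BackgroundStats-class].
#' @export
backgroundStats <- function(structure, k_background = 1L, seed = 1L,
                            chains = NULL, backend = computeFeatures) {
  .bgEnv$calls <- .bgEnv$calls + 1L
  specs <- enumerateSaturation(structure, chains)
  l <- length(specs) %/% 19L
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    ens <- buildMutantEnsemble(structure, specs[[i]], k = k_background,
                               seed = childSeed(seed, paste0("bg", i)))
    rows[[i]] <- .ensembleFeatureMatrix(ens, backend)
  }
  pool <- do.call(rbind, rows)
  colnames(pool) <- FEATURE_NAMES
  new("BackgroundStats",
      U = colMeans(pool),
      S = apply(pool, 2L, popSd),
      pool = pool,
      l = as.integer(l),
      protein_id = structureId(structure),
      seed = as.integer(seed))
}

#' Encode one mutant against its protein's saturation background
#'
#' Builds the 58-element input vector Z from the mutant's averaged feature
#' vector N and the wild-type protein's background statistics:
#' \deqn{v^j = (g^j - \mu^j) / \sigma^j}{v_j = (g_j - mu_j) / sigma_j}
#' (0 when \eqn{\sigma^j = 0}), and \eqn{y^j} the midrank empirical
#' percentile of \eqn{g^j} within background-pool column j (fraction strictly
#' below plus half the fraction tied), in `[0, 1]`. Z is the concatenation
#' `[V; Y]`. Both blocks place the mutant relative to all possible single
#' mutants of the same protein, making vectors comparable across proteins.
#'
#' @param N numeric(29) mutant ensemble-mean feature vector.
#' @param bg [BackgroundStats-class] of the same wild-type protein.
#' @return numeric(58), names `z1..z58`.
#' @export
encodeMutant <- function(N, bg) {
  stopifnot(is(bg, "BackgroundStats"))
  if (length(N) != N_FEATURES)
    stop("feature vector and background schema mismatch")
  if (!is.null(names(N)) && !identical(names(N), FEATURE_NAMES))
    stop("feature vector names do not match the 29-feature schema")
  v <- ifelse(bg@S > 0, (N - bg@U) / bg@S, 0)
  y <- vapply(seq_len(N_FEATURES), function(j)
    midrankPercentile(N[[j]], bg@pool[, j]), numeric(1))
  stats::setNames(c(v, y), paste0("z", seq_len(ENCODED_DIM)))
}

#' Encode a dataset of mutants
#'
#' Runs the full encoding pipeline for a table of mutation records: per
#' protein, background statistics are computed once and reused (cached by
#' protein and seed); per mutant, k stochastic models are built, their
#' features averaged, and the result encoded against the background.
#'
#' @param records data.frame with columns `protein_id`, `mutation_spec`
#'   (string dialect of [parseMutationSpec()]) and `ddg` (kcal/mol).
#' @param structures named list of wild-type [ProteinStructure-class]
#'   objects, names matching `protein_id`.
#' @param k models per mutant (default 10).
#' @param k_background models per background mutant (default 1).
#' @param seed integer RNG seed.
#' @param backend feature backend function.
#' @return data.frame: `protein_id`, `mutation_spec`, `ddg`, `n_sites`,
#'   `z1..z58`.
#' @export
encodeDataset <- function(records, structures, k = 10L, k_background = 1L,
                          seed = 1L, backend = computeFeatures) {
  req <- c("protein_id", "mutation_spec", "ddg")
  if (!all(req %in% names(records)))
    stop("records needs columns: ", paste(req, collapse = ", "))
  if (nrow(records) == 0L)
    return(cbind(records[, req, drop = FALSE], n_sites = integer(0)))
  unknown <- setdiff(unique(records$protein_id), names(structures))
  if (length(unknown))
    stop("no structure for protein(s): ", paste(unknown, collapse = ", "))

  bgCache <- list()
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    pid <- records$protein_id[i]
    if (is.null(bgCache[[pid]]))
      bgCache[[pid]] <- backgroundStats(structures[[pid]],
                                        k_background = k_background,
                                        seed = childSeed(seed, pid),
                                        backend = backend)
    spec <- parseMutationSpec(records$mutation_spec[i])
    ens <- buildMutantEnsemble(structures[[pid]], spec, k = k,
                               seed = childSeed(seed, paste0("mut", i)))
    N <- ensembleMean(asplit(.ensembleFeatureMatrix(ens, backend), 1L))
    z <- encodeMutant(N, bgCache[[pid]])
    out[[i]] <- data.frame(protein_id = pid,
                           mutation_spec = records$mutation_spec[i],
                           ddg = records$ddg[i],
                           n_sites = mutationCount(spec),
                           t(z), check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write encoded datasets
#'
#' Lossless TSV round-trip of the encoded-dataset table
#' (`protein_id`, `mutation_spec`, `ddg`, `n_sites`, `z1..z58`).
#'
#' @param x encoded data.frame (for writing).
#' @param path TSV file path.
#' @return `readEncodedDataset` returns the data.frame; `writeEncodedDataset`
#'   returns `path` invisibly.
#' @name encodedIO
#' @export
writeEncodedDataset <- function(x, path) {
  y <- x
  for (cn in names(y)) if (is.double(y[[cn]])) y[[cn]] <- sprintf("%.17g", y[[cn]])
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname encodedIO
#' @export
readEncodedDataset <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein_id", "mutation_spec", "ddg", "n_sites",
            paste0("z", seq_len(ENCODED_DIM)))
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("encoded dataset missing columns: ", paste(missing, collapse = ", "))
  x
}

# Extract the 58-column feature matrix from an encoded table.
encodedMatrix <- function(data) {
  zc <- paste0("z", seq_len(ENCODED_DIM))
  missing <- setdiff(zc, names(data))
  if (length(missing))
    stop("encoded table missing columns: ", paste(missing, collapse = ", "))
  as.matrix(data[, zc])
}
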