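# Mutation specifications, saturation enumeration and mutant model building.

.siteDF <- function(chain, res_seq, icode, wt, mut) {
  data.frame(chain = as.character(chain), res_seq = as.integer(res_seq),
             icode = as.character(icode), wt = as.character(wt),
             mut = as.character(mut), stringsAsFactors = FALSE)
}

#' Parse a mutation specification string
#'
#' The dialect is `CHAIN:WTPOSMUT`, with several sites joined by `";"`, e.g.
#' `"A:V31I;A:D43N"`. An optional PDB insertion code may follow the position
#' as a lowercase letter (`"A:V31aI"`). Whitespace around tokens is ignored
#' and sites are returned in input order. Newlines are accepted as
#' separators, so a one-mutation-per-line file can be parsed after
#' `paste(readLines(f), collapse = ";")`.
#'
#' @param text non-empty specification string.
#' @return A [MutationSpec-class].
#' @examples
#' parseMutationSpec("A:V31I;A:D43N")
#' @export
parseMutationSpec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\n", ";", text)
  toks <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty mutation specification")
  pat <- "^([A-Za-z0-9]+)\\s*:\\s*([A-Z])([0-9]+)([a-z]?)([A-Z])$"
  m <- regmatches(toks, regexec(pat, toks))
  bad <- which(vapply(m, length, integer(1)) == 0L)
  if (length(bad))
    stop("cannot parse mutation token: '", toks[bad[1]], "'")
  parts <- do.call(rbind, lapply(m, function(g) g[-1]))
  wt <- parts[, 2]; mut <- parts[, 5]
  unknown <- setdiff(c(wt, mut), AA1)
  if (length(unknown))
    stop("unknown amino-acid letter: ", paste(unique(unknown), collapse = ", "))
  if (any(wt == mut))
    stop("silent mutation: ", toks[which(wt == mut)[1]])
  s <- .siteDF(parts[, 1], parts[, 3], toupper(parts[, 4]), wt, mut)
  key <- paste(s$chain, s$res_seq, s$icode)
  if (anyDuplicated(key))
    stop("duplicate mutation site: ", key[duplicated(key)][1])
  new("MutationSpec", sites = s)
}

#' Format a mutation specification as a string
#'
#' Inverse of [parseMutationSpec()].
#'
#' @param spec a [MutationSpec-class].
#' @return character(1) in the `"A:V31I;A:D43N"` dialect.
#' @export
formatMutationSpec <- function(spec) {
  s <- sites(spec)
  paste(sprintf("%s:%s%d%s%s", s$chain, s$wt, s$res_seq,
                tolower(s$icode), s$mut), collapse = ";")
}

# Standard-residue table of a structure: one row per residue whose res_name
# is one of the 20 standard amino acids and which is not a HETATM group.
standardResidues <- function(structure, chains = NULL) {
  r <- residues(structure)
  r <- r[!r$het & r$res_name %in% AA3, , drop = FALSE]
  if (!is.null(chains)) r <- r[r$chain %in% chains, , drop = FALSE]
  r
}

#' Enumerate in-silico single-site saturation mutagenesis
#'
#' Generates every possible single-residue substitution of a protein: for each
#' of the l standard residues (in the selected chains), the 19 mutations to
#' the non-wild-type standard amino acids, giving exactly l x 19 specs.
#' Non-standard residues (HETATM groups, modified residues) are skipped and
#' excluded from l.
#'
#' @param structure a [ProteinStructure-class].
#' @param chains optional character vector restricting the enumeration.
#' @return A list of single-site [MutationSpec-class] objects.
#' @examples
#' s <- generateToyStructure(5, seed = 1)
#' length(enumerateSaturation(s))  # 95
#' @export
enumerateSaturation <- function(structure, chains = NULL) {
  r <- standardResidues(structure, chains)
  if (nrow(r) == 0L) stop("structure has no standard residues to mutate")
  out <- vector("list", nrow(r) * 19L)
  i <- 0L
  for (j in seq_len(nrow(r))) {
    wt <- AA1_FROM_3[[r$res_name[j]]]
    for (mut in AA1[AA1 != wt]) {
      i <- i + 1L
      out[[i]] <- new("MutationSpec",
                      sites = .siteDF(r$chain[j], r$res_seq[j], r$icode[j],
                                      wt, mut))
    }
  }
  out
}

# Ideal C-beta position from backbone N, CA, C (tetrahedral geometry).
idealCBeta <- function(n, ca, c) {
  u1 <- unitVec(n - ca)
  u2 <- unitVec(c - ca)
  bis <- unitVec(u1 + u2)
  perp <- unitVec(cross3(u1, u2))
  ca + 1.53 * unitVec(perp * sin(50 * pi / 180) - bis * cos(50 * pi / 180))
}

# Apply one MutationSpec to a structure: coarse side-chain stand-in.
# The mutated residue keeps backbone + CB (CB synthesised if absent) and the
# new side chain becomes one pseudo-atom ("SCC", carbon) at the residue-type
# mean side-chain length along the CA->CB axis. Returns the structure plus the
# row indices of mutated-residue atoms (for jittering).
applyMutation <- function(structure, spec) {
  a <- atoms(structure)
  s <- sites(spec)
  for (j in seq_len(nrow(s))) {
    sel <- which(a$chain == s$chain[j] & a$res_seq == s$res_seq[j] &
                 a$icode == s$icode[j] & !a$het)
    siteLab <- sprintf("%s:%s%d%s", s$chain[j], s$wt[j], s$res_seq[j],
                       tolower(s$icode[j]))
    if (length(sel) == 0L)
      stop("mutation site not found in structure: ", siteLab)
    resn <- a$res_name[sel[1]]
    if (!resn %in% AA3)
      stop("mutation site is not a standard residue: ", siteLab)
    if (AA1_FROM_3[[resn]] != s$wt[j])
      stop("wild-type mismatch at ", siteLab, ": structure has ",
           AA1_FROM_3[[resn]])

    keep <- sel[a$name[sel] %in% c(BACKBONE_ATOMS, "CB")]
    drop <- setdiff(sel, keep)

    getXYZ <- function(nm) {
      i <- sel[a$name[sel] == nm][1]
      if (is.na(i)) NULL else c(a$x[i], a$y[i], a$z[i])
    }
    ca <- getXYZ("CA"); nn <- getXYZ("N"); cc <- getXYZ("C")
    if (is.null(ca) || is.null(nn) || is.null(cc))
      stop("incomplete backbone at ", siteLab)
    cb <- getXYZ("CB")
    newRows <- .emptyAtoms()
    if (is.null(cb)) {
      cb <- idealCBeta(nn, ca, cc)
      newRows <- rbind(newRows, data.frame(
        name = "CB", element = "C", x = cb[1], y = cb[2], z = cb[3],
        chain = s$chain[j], res_seq = s$res_seq[j], icode = s$icode[j],
        res_name = AA3[[s$mut[j]]], is_backbone = FALSE, het = FALSE,
        stringsAsFactors = FALSE))
    }
    len <- SIDECHAIN_LENGTH[[s$mut[j]]]
    if (len > 0) {
      scc <- cb + len * unitVec(cb - ca)
      newRows <- rbind(newRows, data.frame(
        name = "SCC", element = "C", x = scc[1], y = scc[2], z = scc[3],
        chain = s$chain[j], res_seq = s$res_seq[j], icode = s$icode[j],
        res_name = AA3[[s$mut[j]]], is_backbone = FALSE, het = FALSE,
        stringsAsFactors = FALSE))
    }
    a$res_name[keep] <- AA3[[s$mut[j]]]
    if (length(drop)) {
      a <- a[-drop, , drop = FALSE]
    }
    # insert new atoms right after the residue's retained atoms
    if (nrow(newRows)) {
      last <- max(which(a$chain == s$chain[j] & a$res_seq == s$res_seq[j] &
                        a$icode == s$icode[j] & !a$het))
      a <- rbind(a[seq_len(last), , drop = FALSE], newRows,
                 if (last < nrow(a)) a[(last + 1):nrow(a), , drop = FALSE])
    }
    rownames(a) <- NULL
  }
  mutIdx <- which(paste(a$chain, a$res_seq, a$icode) %in%
                    paste(s$chain, s$res_seq, s$icode) & !a$het)
  list(atoms = a, mutated_rows = mutIdx)
}

#' Build a stochastic ensemble of mutant structural models
#'
#' Applies a mutation specification to a wild-type structure and produces k
#' models of the mutant. Mutated residues keep backbone + C-beta (synthesised
#' at ideal tetrahedral geometry when absent, e.g. glycine) and carry the new
#' side chain as a single pseudo-atom at the residue-type mean side-chain
#' length along the CA->CB direction. Model-to-model diversity comes from
#' Gaussian coordinate jitter (sd 0.15 Angstrom) applied to mutated-residue
#' atoms only, drawn from a seeded stream: a fixed
#' `(structure, spec, k, seed)` always reproduces the same ensemble, and
#' unmutated residues are bit-identical to the wild type.
#'
#' @param structure wild-type [ProteinStructure-class].
#' @param spec a [MutationSpec-class]; wild-type letters must match the
#'   structure at every site.
#' @param k number of models (>= 1); default 10.
#' @param seed integer RNG seed.
#' @param jitter_sd jitter standard deviation in Angstrom.
#' @return A [MutantEnsemble-class].
#' @examples
#' s <- generateToyStructure(8, seed = 2)
#' wt <- residues(s)$res_name[1]
#' spec <- parseMutationSpec(sprintf("A:%s1%s", AA1_FROM_3[[wt]],
#'                                   setdiff(c("L", "V"), AA1_FROM_3[[wt]])[1]))
#' ens <- buildMutantEnsemble(s, spec, k = 3, seed = 7)
#' @export
buildMutantEnsemble <- function(structure, spec, k = 10L, seed = 1L,
                                jitter_sd = 0.15) {
  stopifnot(is(structure, "ProteinStructure"), is(spec, "MutationSpec"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  base <- applyMutation(structure, spec)
  models <- withSeed(seed, {
    lapply(seq_len(k), function(i) {
      a <- base$atoms
      rows <- base$mutated_rows
      nj <- length(rows)
      a$x[rows] <- a$x[rows] + stats::rnorm(nj, 0, jitter_sd)
      a$y[rows] <- a$y[rows] + stats::rnorm(nj, 0, jitter_sd)
      a$z[rows] <- a$z[rows] + stats::rnorm(nj, 0, jitter_sd)
      newStructure(paste0(structureId(structure), "_mut", i), a)
    })
  })
  new("MutantEnsemble", spec = spec, models = models, seed = as.integer(seed))
}
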