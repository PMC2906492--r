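# The 29 structural features: coarse geometric backend and TSV loader.
#
# The feature LIST (13 energy-style terms, 3 potential terms, 13 distance-bin
# frequencies) is fixed; the built-in formulas are coarse geometric stand-ins
# for the external energy calculators that normally supply these numbers.
# Every term is a function of interatomic distances/angles only, so the whole
# vector is invariant under rigid motion. Users with access to a real energy
# engine can bypass this backend entirely via loadFeatureTable().

#' The 29-feature schema
#'
#' Returns the ordered labels of the 29 structural features: 13 energy-style
#' terms, 3 stereochemical potential terms, and 13 distance-bin frequencies
#' with 0.1-Angstrom bins spanning 2.1--3.3 A (first bin `[0, 2.1)`).
#'
#' @return character(29).
#' @export
featureSchema <- function() FEATURE_NAMES

# ---- geometry helpers -------------------------------------------------------

.heavy <- function(a) a[a$element != "H", , drop = FALSE]

.coordMat <- function(a) cbind(a$x, a$y, a$z)

# Pairwise distance matrix of an atom table.
.distMat <- function(a) as.matrix(stats::dist(.coordMat(a)))

# Covalent-bond adjacency by distance rule: heavy pairs closer than 1.9 A
# (2.2 A when sulfur is involved) are treated as bonded.
.bondMat <- function(a, D) {
  cut <- matrix(1.9, nrow(a), nrow(a))
  isS <- a$element == "S"
  cut[isS, ] <- 2.2; cut[, isS] <- 2.2
  B <- D < cut
  diag(B) <- FALSE
  B
}

# Side-chain centroid (heavy atoms not in the backbone) per residue; falls
# back to CA for glycine. Returns a matrix with rows aligned to `res`.
.sidechainCentroids <- function(a, res) {
  out <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    sel <- a$chain == res$chain[i] & a$res_seq == res$res_seq[i] &
      a$icode == res$icode[i] & a$element != "H"
    sc <- a[sel & !a$is_backbone, , drop = FALSE]
    if (nrow(sc) == 0L) sc <- a[sel & a$name == "CA", , drop = FALSE]
    if (nrow(sc) > 0L) out[i, ] <- colMeans(.coordMat(sc))
  }
  out
}

# ---- individual feature groups ---------------------------------------------

#' Distance-bin frequencies
#'
#' Histogram of non-covalent heavy-atom pair distances, as 13 shares. The
#' population is all heavy-atom pairs that are not covalently bonded
#' (distance rule; covers both intra- and inter-residue bonds) and closer
#' than 6 Angstrom. Each bin holds the fraction of that population falling in
#' `[0,2.1), [2.1,2.2), ..., [3.2,3.3)`; pairs at 3.3 A or beyond count only
#' in the denominator. With no eligible pairs all bins are 0.
#'
#' @param structure a [ProteinStructure-class] with >= 2 heavy atoms.
#' @return numeric(13) in `[0, 1]`, summing to at most 1.
#' @export
distanceBinFrequencies <- function(structure) {
  a <- .heavy(atoms(structure))
  if (nrow(a) < 2L) stop("need at least 2 heavy atoms")
  D <- .distMat(a)
  B <- .bondMat(a, D)
  ut <- upper.tri(D)
  elig <- ut & !B & D < 6
  total <- sum(elig)
  if (total == 0L) return(stats::setNames(rep(0, 13L), FEATURE_NAMES[17:29]))
  d <- D[elig]
  counts <- vapply(seq_len(13L), function(i)
    sum(d >= FREQ_BIN_EDGES[i] & d < FREQ_BIN_EDGES[i + 1L]), numeric(1))
  stats::setNames(counts / total, FEATURE_NAMES[17:29])
}

#' Count geometric hydrogen bonds
#'
#' Counts donor--acceptor pairs of N/O atoms from different residues at
#' 2.5--3.5 Angstrom separation, split into backbone (both atoms are backbone
#' N/O) and side-chain (any other) contacts. A geometric stand-in: no
#' hydrogen positions or angles are used.
#'
#' @param structure a [ProteinStructure-class].
#' @return named numeric(2): `backbone`, `sidechain`.
#' @export
countHBonds <- function(structure) {
  a <- atoms(structure)
  a <- a[a$element %in% c("N", "O"), , drop = FALSE]
  if (nrow(a) < 2L) return(c(backbone = 0, sidechain = 0))
  D <- .distMat(a)
  res <- paste(a$chain, a$res_seq, a$icode)
  sameRes <- outer(res, res, "==")
  hb <- upper.tri(D) & !sameRes & D >= 2.5 & D <= 3.5
  bb <- outer(a$is_backbone, a$is_backbone, "&")
  c(backbone = sum(hb & bb), sidechain = sum(hb & !bb))
}

# Clash counts: pairs closer than (vdW sum - 0.4) [clashes] or 0.8 * vdW sum
# [hard clashes, split into backbone-backbone vs side-chain-involving].
.clashCounts <- function(a, D, B) {
  r <- VDW_RADII[a$element]
  r[is.na(r)] <- 1.7
  vsum <- outer(r, r, "+")
  ut <- upper.tri(D) & !B
  soft <- sum(ut & D < (vsum - 0.4))
  hard <- ut & D < (0.8 * vsum)
  bb <- outer(a$is_backbone, a$is_backbone, "&")
  list(soft = soft, hard_bb = sum(hard & bb), hard_sc = sum(hard & !bb))
}

# Coulomb sum over charged side-chain centroids: Asp/Glu -1, Lys/Arg +1,
# His +0.5; 10 A cutoff, dielectric 40, 332 kcal*A/(mol*e^2).
.electrostatics <- function(a, res, centroids) {
  aa1 <- AA1_FROM_3[res$res_name]
  q <- SIDECHAIN_CHARGE[aa1]
  sel <- which(!is.na(q) & !is.na(centroids[, 1]))
  if (length(sel) < 2L) return(0)
  ce <- centroids[sel, , drop = FALSE]
  qq <- q[sel]
  e <- 0
  for (i in seq_len(length(sel) - 1L)) {
    dv <- sqrt(colSums((t(ce[(i + 1):length(sel), , drop = FALSE]) - ce[i, ])^2))
    ok <- dv < 10 & dv > 1e-6
    e <- e + sum(332 * qq[i] * qq[(i + 1):length(sel)][ok] / (40 * dv[ok]))
  }
  e
}

# Solvent-exposure proxy: mean number of heavy atoms (other residues) within
# 8 A of polar / apolar side-chain centroids.
.solvationProxies <- function(a, res, centroids) {
  ha <- .heavy(a)
  xyz <- .coordMat(ha)
  resKey <- paste(ha$chain, ha$res_seq, ha$icode)
  neigh <- function(aaSet) {
    aa1 <- AA1_FROM_3[res$res_name]
    sel <- which(aa1 %in% aaSet & !is.na(centroids[, 1]))
    if (length(sel) == 0L) return(0)
    cnt <- vapply(sel, function(i) {
      d <- sqrt(colSums((t(xyz) - centroids[i, ])^2))
      own <- resKey == paste(res$chain[i], res$res_seq[i], res$icode[i])
      sum(d < 8 & !own)
    }, numeric(1))
    mean(cnt)
  }
  c(polar = neigh(POLAR_AA), hydrophobic = neigh(APOLAR_AA))
}

# Rotamer-count log proxies for conformational entropy.
.entropyProxies <- function(res) {
  aa1 <- AA1_FROM_3[res$res_name]
  aa1 <- aa1[!is.na(aa1)]
  sc <- sum(log(3^N_CHI[aa1] + 1))
  w <- BB_FLEX[aa1]
  w[is.na(w)] <- 1
  mc <- sum(log(1 + w))
  c(side = sc, main = mc)
}

# Helices by the i -> i+4 backbone H-bond pattern; the dipole proxy is the
# net formal side-chain charge within 6 A of the C-terminal minus the
# N-terminal helix end (negative charge near the N-terminus stabilises).
.helixDipole <- function(a, res, centroids) {
  bbO <- a[a$name == "O" & a$is_backbone, , drop = FALSE]
  bbN <- a[a$name == "N" & a$is_backbone, , drop = FALSE]
  keyO <- paste(bbO$chain, bbO$res_seq, bbO$icode)
  keyN <- paste(bbN$chain, bbN$res_seq, bbN$icode)
  resKey <- paste(res$chain, res$res_seq, res$icode)
  iO <- match(keyO, resKey)
  hbond14 <- logical(nrow(res))
  for (j in seq_along(iO)) {
    i <- iO[j]
    if (is.na(i) || i + 4L > nrow(res)) next
    if (res$chain[i + 4L] != res$chain[i]) next
    k <- which(keyN == resKey[i + 4L])
    if (length(k) == 0L) next
    d <- sqrt(sum((c(bbO$x[j], bbO$y[j], bbO$z[j]) -
                   c(bbN$x[k[1]], bbN$y[k[1]], bbN$z[k[1]]))^2))
    if (d >= 2.5 && d <= 3.5) hbond14[i] <- TRUE
  }
  runs <- rle(hbond14)
  if (!any(runs$values)) return(0)
  aa1 <- AA1_FROM_3[res$res_name]
  q <- SIDECHAIN_CHARGE[aa1]
  q[is.na(q)] <- 0
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  caXYZ <- function(i) {
    sel <- a$name == "CA" & paste(a$chain, a$res_seq, a$icode) == resKey[i]
    if (!any(sel)) return(NULL)
    c(a$x[sel][1], a$y[sel][1], a$z[sel][1])
  }
  chargeNear <- function(p) {
    if (is.null(p)) return(0)
    ok <- which(!is.na(centroids[, 1]) & q != 0)
    if (length(ok) == 0L) return(0)
    d <- sqrt(colSums((t(centroids[ok, , drop = FALSE]) - p)^2))
    sum(q[ok][d < 6])
  }
  dip <- 0
  for (r in which(runs$values)) {
    nterm <- starts[r]
    cterm <- min(ends[r] + 4L, nrow(res))
    dip <- dip + chargeNear(caXYZ(cterm)) - chargeNear(caXYZ(nterm))
  }
  dip
}

# Harmonic stereochemical terms from detected covalent bonds.
.stereoTerms <- function(a, D, B) {
  idx <- which(upper.tri(B) & B, arr.ind = TRUE)
  bondE <- 0
  if (nrow(idx)) {
    pair <- apply(idx, 1L, function(ij)
      paste(sort(c(a$element[ij[1]], a$element[ij[2]])), collapse = "-"))
    r0 <- IDEAL_BOND[pair]
    r0[is.na(r0)] <- 1.5
    bondE <- sum((D[idx] - r0)^2) * 100
  }
  # angle deviations at atoms with >= 2 bonded neighbours
  angleE <- 0
  improperE <- 0
  xyz <- .coordMat(a)
  for (i in seq_len(nrow(a))) {
    nb <- which(B[i, ])
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(prs))) {
      v1 <- xyz[prs[1, p], ] - xyz[i, ]
      v2 <- xyz[prs[2, p], ] - xyz[i, ]
      cs <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
      th <- acos(pmin(1, pmax(-1, cs))) * 180 / pi
      dev2 <- (th - 109.5)^2 * 0.01
      angleE <- angleE + dev2
      if (a$name[i] == "CA" &&
          all(a$name[prs[, p]] %in% c("N", "C", "CB")))
        improperE <- improperE + (th - 111)^2 * 0.01
    }
  }
  c(bond = bondE, current = bondE + angleE, improper = improperE)
}

#' Compute the 29 structural features of a structure model
#'
#' The built-in coarse geometric backend: counts and harmonic proxies standing
#' in for external energy-calculator outputs, plus the 13 distance-bin
#' frequencies. Deterministic for a fixed structure and invariant under rigid
#' motion. The "Total energy" term is the sum of the other 12 energy-style
#' terms.
#'
#' @param structure a [ProteinStructure-class] with >= 2 atoms.
#' @return named numeric(29) aligned to [featureSchema()]; the `source`
#'   attribute records the backend.
#' @examples
#' f <- computeFeatures(generateToyStructure(6, seed = 3))
#' f[["Backbone H-bond"]]
#' @export
computeFeatures <- function(structure) {
  a0 <- atoms(structure)
  if (nrow(a0) < 2L) stop("pairwise terms undefined: structure has < 2 atoms")
  a <- .heavy(a0)
  if (nrow(a) < 2L) stop("pairwise terms undefined: < 2 heavy atoms")
  D <- .distMat(a)
  B <- .bondMat(a, D)
  res <- residues(structure)
  res <- res[res$res_name %in% AA3 & !res$het, , drop = FALSE]
  centroids <- if (nrow(res)) .sidechainCentroids(a, res) else
    matrix(NA_real_, 0, 3)

  hb <- countHBonds(structure)
  cl <- .clashCounts(a, D, B)
  elec <- if (nrow(res)) .electrostatics(a, res, centroids) else 0
  solv <- if (nrow(res)) .solvationProxies(a, res, centroids) else
    c(polar = 0, hydrophobic = 0)
  ent <- if (nrow(res)) .entropyProxies(res) else c(side = 0, main = 0)
  dip <- if (nrow(res)) .helixDipole(a, res, centroids) else 0
  st <- .stereoTerms(a, D, B)
  freq <- distanceBinFrequencies(structure)

  # favourable-contact proxy for the attractive vdW term (negative = better)
  r <- VDW_RADII[a$element]; r[is.na(r)] <- 1.7
  vsum <- outer(r, r, "+")
  ut <- upper.tri(D) & !B
  vdw <- -sum(ut & D >= vsum & D < (vsum + 1.0))

  e <- c(hb[["backbone"]], hb[["sidechain"]], vdw, elec,
         solv[["polar"]], solv[["hydrophobic"]], cl$soft,
         ent[["side"]], ent[["main"]], cl$hard_sc, cl$hard_bb, dip)
  vals <- c(sum(e), e, st[["current"]], st[["bond"]], st[["improper"]], freq)
  vals <- stats::setNames(as.numeric(vals), FEATURE_NAMES)
  stopifnot(all(is.finite(vals)))
  attr(vals, "source") <- "geometric"
  vals
}

#' Load precomputed feature tables
#'
#' Reads a TSV of precomputed 29-feature vectors (e.g. from an external
#' energy calculator) keyed by a `model_id` column. Columns may appear in any
#' order; they are re-aligned to the canonical [featureSchema()] order. Extra
#' columns are ignored with a warning.
#'
#' @param path TSV file with a header row naming `model_id` plus the 29
#'   schema features.
#' @return named list of numeric(29) vectors, one per `model_id`.
#' @export
loadFeatureTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"model_id" %in% names(tab)) stop("feature table needs a model_id column")
  missing <- setdiff(FEATURE_NAMES, names(tab))
  if (length(missing))
    stop("feature table missing columns: ", paste(missing, collapse = "; "))
  extra <- setdiff(names(tab), c("model_id", FEATURE_NAMES))
  if (length(extra))
    warning("ignoring extra feature-table columns: ",
            paste(extra, collapse = ", "))
  for (cn in FEATURE_NAMES) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", cn, "', row ", bad)
    }
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    v <- stats::setNames(as.numeric(tab[i, FEATURE_NAMES]), FEATURE_NAMES)
    attr(v, "source") <- "table"
    v
  })
  stats::setNames(out, as.character(tab$model_id))
}
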